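# atnav — semi-automated navigation for array-tomography serial sections

Array tomography images ribbons of serial ultrathin (~150 nm) sections
deposited on a conductive coverslip and stacks the per-section images into a
3D volume. The practical bottleneck is navigation: a region of interest
(ROI) — an organelle, a labelled cell, a condensate — must be found again in
every one of a hundred-plus sections, at magnifications from a 20x
brightfield overview to 30kx electron imaging, while the sections gradually
change shape along each ribbon. `atnav` implements the full navigation
workflow for this problem, aimed at microscopists running integrated
light/electron (iLEM) or correlative acquisitions:

1. **Overview** — stitch a grid of 20x brightfield tiles (~20 % overlap)
   into one navigation mosaic (`grid_stitch`), and anchor absolute stage
   coordinates by zeroing the stage on a section corner
   (`calibrate_stage`).
2. **Detection** — preprocess the overview into an edge-response map
   (`preprocess_overview`: contrast normalisation, Gaussian blur, Laplacian,
   Otsu threshold, size filter, morphological smoothing) and fit a
   quadrilateral active contour to every section, walking outward along each
   ribbon from a single user-sketched seed (`detect_all_sections`).
3. **ROI propagation** — address an ROI by its *natural coordinates*
   (ξ, η) ∈ [−1, 1]² on the 4-node isoparametric reference square. The
   transfinite (bilinear) map

   x(ξ,η) = Σᵢ Nᵢ(ξ,η) xᵢ,  N₁ = (1−ξ)(1−η)/4, N₂ = (1+ξ)(1−η)/4,
   N₃ = (1+ξ)(1+η)/4, N₄ = (1−ξ)(1+η)/4

   links every detected quadrilateral to the reference square, so a point
   picked in one section re-materialises at the same relative address in
   every other section regardless of shrink, shear or tilt
   (`forward_map`, `inverse_map`, `propagate_roi`).
4. **Focus** — interpolate a focus surface from a handful of manually
   focused anchor points by exact Sibson natural-neighbour interpolation
   (`focus_map`, `interpolate_focus`).
5. **Planning and acquisition** — generate a resumable per-ROI,
   per-section, per-magnification navigation plan with stage targets and
   focus values (`build_plan`, JSON on disk), and execute it against a
   microscope interface (`acquire_stack`); interrupted runs resume from the
   plan file.
6. **Stepwise refinement** — register each acquired stack by subpixel phase
   correlation (`register_stack`), and feed the per-section shifts back
   into the stage targets of the next magnification
   (`refine_plan`), so accuracy improves at every rung of the
   20x → 100x → 4kx → 12kx → 30kx ladder.

No microscope is required to use or test any of this: a fully seeded
synthetic module (`generate_scene`, `render_overview`, `degrade_image`,
`simulated_microscope`) generates ribbons of trapezoidal sections with
ground-truth geometry, drifting dark ROI structures, a focus surface and a
simulated multi-magnification microscope with stage-repeatability jitter.

## Worked example

```r
library(atnav)

scene    <- generate_scene(list(n_ribbons = 2L, sections_total = 10L,
                                sections_range = c(4L, 6L)), seed = 3)
overview <- render_overview(scene, px_per_um = 2.96)
edge     <- preprocess_overview(overview)

truth      <- attr(overview, "truth_px")             # a user would sketch these
seed_quads <- lapply(truth, function(rb) rb[[ceiling(length(rb) / 2)]])
det        <- detect_all_sections(edge, seed_quads)
det
#> detection_result: 2 ribbon(s), 6+4 sections

cal  <- calibrate_stage(origin_px = unclass(det$ribbons[[1]]$sections[[1]])[1, ],
                        pixel_size = 1 / 2.96)
roi  <- define_roi("golgi-1", det, ribbon = 1, anchor_section = 1,
                   anchor_point_px = quad_centroid(det$ribbons[[1]]$sections[[1]]) + c(5, -8))
round(roi$natural, 3)
#> [1]  0.062 -0.118
plan <- build_plan(roi, det, cal, focus = NULL, mags = c("20x", "100x"),
                   n_sections = 6)
head(plan$entries[plan$entries$mag == "20x", c("section", "x_um", "y_um", "status")])
#>    section     x_um      y_um  status
#> 1        1 32.14888  18.97135 pending
#> 3        2 33.40454  66.82831 pending
#> 5        3 34.77001 114.76436 pending
#> 7        4 36.11426 162.45116 pending
#> 9        5 37.30957 210.22877 pending
#> 11       6 38.56522 257.74789 pending
```

The two ribbons are detected in full from one rough seed each, the ROI is
addressed by its natural coordinates (0.062, −0.118), and the plan predicts
its stage position in all six requested sections — the ~48 µm step in y is
the ribbon pitch. `run_pipeline()` drives the same chain end to end against
the simulated microscope, including both acquisition rounds, registration,
and the correction CSVs.

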