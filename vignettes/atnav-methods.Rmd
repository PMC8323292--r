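---
title: "Methods: section detection, transfinite ROI propagation, and stepwise refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: section detection, transfinite ROI propagation, and stepwise refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnav)
```

`atnav` navigates ribbons of serial ultrathin sections: given one
brightfield overview of the coverslip, it finds every section, addresses a
region of interest (ROI) in section-shape-independent coordinates, plans
stage moves for the whole ribbon across a magnification ladder, and uses
stack registration as feedback to refine those moves. This vignette is the
package's account of the underlying models, the parameters that matter,
the numerical choices, and the limits of what the synthetic test harness
demonstrates.

## The transfinite (bilinear isoparametric) map

Each section is modelled as a simple quadrilateral with positive shoelace
area, corners ordered counter-clockwise in image coordinates starting at
the leading (first-cut) edge. The map between a section and the reference
square uses the standard 4-node element shape functions on
$[-1,1]^2$; `forward_map()` is $\sum_i N_i(\xi,\eta)\,x_i$. Because the
$N_i$ sum to one everywhere, the map is exactly affine-equivariant: if two
sections differ by any affine transform, ROI propagation between them is
exact. What the bilinear map adds over a rigid or affine registration is
the ability to absorb the independent motion of the four corners —
trapezoid taper, progressive shrink and shear — while preserving relative
position inside the section.

Numerical choices:

* The source text this workflow derives from does not fix the range of the
  natural coordinates or the numbering of the shape functions; $[-1,1]^2$
  with the standard counter-clockwise numbering is the package's
  convention.
* `inverse_map()` solves the 2×2 bilinear system by damped Newton from the
  element centre $(0,0)$ (inversion of a bilinear map is quadratic, so
  Newton from the centroid converges in a handful of iterations for convex
  quads); tolerance $10^{-9}$ in frame units, cap 50 iterations. If
  Newton stalls — possible for strongly non-convex quads — the solver
  reseeds from the best of a 41×41 grid over the reference square,
  preferring seeds nearest the centre, and restarts.
* Non-convex (but simple) quads are accepted with a warning; the inversion
  can be multivalued there, and the returned root is the one closest to
  the centre, flagged via the `multivalued` attribute.

## Overview preprocessing and the edge map

The detection operates on an edge-response map, not on the raw overview.
The pipeline (each stage switchable) is: percentile contrast stretch
(0.5–99.5 %), Gaussian blur (`sigma_blur` = 1.5 px), Laplacian, Otsu
threshold, connected-component size filter (`min_area` = 100 px²),
morphological closing (disc, 5 px), then the Laplacian response gated by
the cleaned mask and smoothed (`sigma_basin` = 1.5 px) so the active
contour sees wide basins. Executed stages and their parameters are
recorded in the result's `stages` attribute, so a run can be reproduced
from its artefacts.

One detail matters: sections and their outlines are *darker* than the
substrate, so boundary lines are intensity minima and carry a positive
Laplacian lobe at their centre. The default response keeps only that
positive part (`laplacian_sign = "positive"`). Taking the magnitude
instead would also fire on bright ridges — notably the bright seam between
two adjacent sections — and pull contours toward the middle of the seam;
with the signed response the crest of the edge map sits on the boundary
centreline to sub-pixel accuracy. The percentile stretch makes the map
invariant to global affine intensity changes.

## Quadrilateral active contour

`fit_active_contour()` minimises

$$E = -\langle \text{edge response along the perimeter} \rangle
      + \lambda_{\text{shape}} \cdot d_{\text{shape}}$$

where $d_{\text{shape}}$ is the mean relative deviation of the four side
lengths plus the mean corner-angle deviation (in right angles) from the
init. The reference energy of the original tool is not public, so the
package uses the simplest model honouring the documented behaviour — a
quad-constrained snake with a shape prior, which tolerates missing corners
and partially erased sides because the remaining perimeter still dominates
the mean.

The optimiser is deliberately plain: coordinate-wise greedy search moving
single corners, whole sides, and the whole quad by 1 px steps, iterated to
convergence inside a 3-level image pyramid (×4, ×2, ×1; each coarse level
is re-smoothed with a 1 px Gaussian so its basins stay wide). Ties break
toward the smallest displacement from the init. The final result is
compared against the init at full resolution and the init is returned if
refinement did not lower the energy, so the fit is monotone by
construction. Fits that shrink below 25 % of the init area are rejected as
degenerate and returned as the init with a flag. `lambda_shape` defaults
to 0.3; `search_radius` (20 px) bounds the wander per fit.

`detect_all_sections()` grows each ribbon in both directions from one
user-sketched seed, alternating prediction and fitting. The first step
away from the seed has no observed pitch, and the seed's own height
underestimates the true pitch by the seam width, so the walk scans the
perimeter response along the ribbon axis (0.85–1.45 × the seed height) and
starts at the best-supported offset; afterwards each prediction is the
last fit translated by the last centroid step with full per-corner drift
extrapolation, which carries shrink and shear forward. A ribbon ends when
the fit score (mean perimeter response) falls below `reject_frac` (0.4) of
the best score seen in that ribbon, when the prediction leaves the image,
or when the contour stops advancing consistently (centroid step outside
0.4–1.8 × the predicted pitch). Scoring against the running best rather
than the seed makes the stop rule robust to a mediocre seed fit.

## Focus surface

`interpolate_focus()` implements Sibson natural-neighbour interpolation
exactly rather than on a raster: the Voronoi cell the query would acquire
on insertion is built by half-plane clipping against all anchors, then
intersected with each anchor's own cell; the stolen areas are the weights.
This gives exactness at anchors and linear precision (planes are
reproduced to machine precision), and the interpolant is bounded by the
anchor range inside the hull. Outside the hull — where the inserted cell
is unbounded and Sibson weights are not defined — the nearest anchor's
focus is returned and the query flagged; with fewer than three
non-collinear anchors the same fallback applies everywhere. The cost is
$O(n^2)$ per query, which is irrelevant at focus-map sizes (tens of
anchors).

## Navigation, acquisition, refinement

Stage calibration is a similarity map: the user zeroes the stage on a
section corner, and `px_to_stage()` applies
`axis_signs * (p - origin_px) * pixel_size`. The stage frame is
+x = image right, +y = image down by default, with `axis_signs`
configurable because hardware conventions differ. Pixel sizes per
magnification default to 20x = 2.96, 100x = 15.38, 4kx = 43.03,
12kx = 129.08, 30kx = 322.69 px/µm, all overridable.

Plans are flat entry tables — (roi, section, magnification, target, focus,
status) — serialized to JSON after every acquired entry, so a run is
resumable and idempotent: only `pending` entries execute. Multi-ROI plans
are by construction the concatenation of independent single-ROI plans,
which is what makes LM-phase multiplexing of several ROIs safe. A
`settle_s` wait (default 2 s, metadata in simulation) separates stage
moves from acquisition, for stages whose focus needs time to stabilise.
Entries are ordered by section within ROI; the alternative interleaving is
exposed via `order_by = "section"`.

Registration is chained pairwise phase correlation — neighbouring sections
are the most similar, and similarity decays with distance along the
ribbon — with subpixel refinement by an upsampled matrix DFT around the
peak (0.1 px). Spectral whitening can produce alias peaks on self-similar
content, so the strongest few peaks are validated against the real-space
Pearson correlation of the actual overlap and the best-supported peak
wins; that correlation doubles as the confidence value. Pairs below
`min_confidence` (0.15) or with shifts beyond 25 % of the frame
(physically implausible between consecutive sections) contribute zero
shift and are flagged. Translation-only is the default; a coarse ±5°
rotation search is available but rotations are never fed back to the
stage.

`refine_plan()` adds `axis_signs * shift_px * pixel_size` to every entry
of the registered ROI at magnifications at or above the next rung, and
logs per-section corrections as $(\Delta x, \Delta y,
\sqrt{\Delta x^2+\Delta y^2})$ µm, written as CSV. The measured correction
field is denoised with a centered running mean over 3 sections
(`smooth_window`; 1 disables): the true navigation-error field varies
smoothly along a ribbon (propagation error and ROI drift change gradually)
while stage-repeatability error is independent white noise per frame, so a
short linear smoother removes most of the jitter without biasing the
drift, and — being linear — preserves the additivity and zero-idempotence
of corrections. With a 1 µm repeatability stage this is the difference
between corrections that are jitter-limited at ~5 µm worst-case and
corrections below ~3.5 µm.

## The synthetic scene: what it emulates, and what it does not

The generator's defaults are the study conditions: 6 ribbons totalling 126
trapezoidal sections (15–27 per ribbon), ribbons roughly parallel to the
image y axis (tilt up to ±2° by default; up to 45° and per-section
curvature available as stressors), per-section shrink 0.2 %, shear
accumulating at 0.0015 per section, glue strips on the leading and
trailing edges, one persistent dark Golgi-like structure per ROI whose
centroid drifts by at most 0.5 µm per section, a smooth focus surface with
~8 µm relief, and an 8-bit overview rendered at 2.96 px/µm. Section faces
are 60 × 45 µm with a 3 µm visible seam between glued sections — the
source does not state section dimensions; these were chosen once so the
full 126-section layout renders desk-scale (~2000 × 4100 px, comfortably
inside a 22 × 22 mm coverslip) and were not revisited. Degradation
operators reproduce the robustness protocol: additive Gaussian noise
(σ in 8-bit gray levels), salt-and-pepper, erasure of 1–4 corners or sides
per section, and dark glue blobs.

Two rendering decisions carry the test burden:

* All texture is a deterministic function of stage coordinates (seeded
  value noise, octave lattices mutually rotated so no common periodicity
  survives), so windows rendered at different centres and magnifications
  agree where they overlap — a requirement for testing stitching and
  registration against ground truth.
* Interior texture is anchored to each section's centroid and blended
  between depth layers that decorrelate over ~8 sections, emulating serial
  sections cutting through continuous 3D structure. Without this,
  consecutive frames would share nothing but the ROI blobs and
  stack registration would have no physical signal to work with.

What passing tests on this scene do **not** show: real tissue contrast
(the renderer's intensity model is stylised), stitching shading/flat-field
artefacts, section folds, wrinkles or debris, electron-optical distortions
at EM magnifications, and focus behaviour beyond a smooth surface. The
acceptance-level numbers (detection error under noise, end-to-end residual
error) are statements about the synthetic twin under the stated
conditions, not measurements on a microscope.

## Problem sizes and tolerances used in the checks

The end-to-end refinement check runs one 20-section ribbon, 20x and 100x
acquisitions at 200 px field of view, stage jitter σ = 1 µm, and the
default drift bound; the noise-robustness and full-layout checks run the
full 126-section overview. Geometry tests use tolerances matched to the
algorithmic guarantees (round-trips at $10^{-8}$, affine equivariance at
float precision, grid-search oracle at $2\times10^{-3}$, Sibson linear
precision at $10^{-6}$); image-level tests assert the behaviourally
meaningful bounds (sub-2 px detection on clean renders, 0.5 px subpixel
registration, 1 px stitching offsets).

## Known limitations

Only quadrilateral sections are supported. The active contour assumes the
preprocessing leaves section boundaries as crests of the edge map; heavy
shading gradients would need a flat-field stage that the package does not
provide. Ribbon walking assumes sections advance monotonically along the
ribbon axis; a ribbon that folds back on itself would terminate the walk
early rather than mis-detect. Registration feedback corrects translation
only — rotating stages and non-rigid section deformation at high EM
magnification are out of scope.
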