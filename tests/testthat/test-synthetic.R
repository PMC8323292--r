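test_that("scene generation is deterministic in (params, seed)", {
  s1 <- generate_scene(list(n_ribbons = 2L, sections_total = 8L,
                            sections_range = c(3L, 5L)), seed = 17L)
  s2 <- generate_scene(list(n_ribbons = 2L, sections_total = 8L,
                            sections_range = c(3L, 5L)), seed = 17L)
  expect_identical(s1, s2)
  s3 <- generate_scene(list(n_ribbons = 2L, sections_total = 8L,
                            sections_range = c(3L, 5L)), seed = 18L)
  expect_false(identical(s1$ribbons, s3$ribbons))
})

test_that("the default layout matches the study sample", {
  sc <- fixture("default_scene", function() generate_scene(seed = 1L))
  expect_equal(length(sc$ribbons), 6)
  expect_equal(sum(sc$section_counts), 126)
  expect_true(all(sc$section_counts >= 15 & sc$section_counts <= 27))
  # fits a 22 x 22 mm coverslip
  expect_lt(diff(sc$bounds$xlim), 22000)
  expect_lt(diff(sc$bounds$ylim), 22000)
  # ROI trajectories: one point per section, drift bounded per step
  roi <- sc$rois[[1]]
  expect_equal(nrow(roi$trajectory), sc$section_counts[roi$ribbon])
  nat_base <- t(vapply(sc$ribbons[[roi$ribbon]]$sections,
                       function(q) forward_map(q, roi$natural), numeric(2)))
  drift <- roi$trajectory - nat_base
  expect_lt(max(sqrt(rowSums(diff(drift)^2))), 0.5 + 1e-9)
})

test_that("zero shrink and curvature give congruent sections", {
  sc <- generate_scene(list(n_ribbons = 1L, sections_total = 5L,
                            sections_range = c(5L, 5L),
                            shrink_per_section = 0, shear_per_section = 0,
                            curvature_deg_per_section = 0), seed = 2L)
  side_lengths <- function(q) {
    nn <- c(2, 3, 4, 1); sqrt(rowSums((unclass(q)[nn, ] - unclass(q))^2))
  }
  ref <- side_lengths(sc$ribbons[[1]]$sections[[1]])
  for (q in sc$ribbons[[1]]$sections)
    expect_equal(side_lengths(q), ref, tolerance = 1e-9)
})

test_that("an infeasible layout raises a layout error", {
  expect_error(generate_scene(list(n_ribbons = 2L, sections_total = 100L,
                                   sections_range = c(3L, 5L))), "layout")
})

test_that("rendered corners project consistently to pixel coordinates", {
  ov <- small_overview()
  sc <- small_scene()
  origin <- attr(ov, "origin_um")
  truth <- attr(ov, "truth_px")
  q_um <- unclass(sc$ribbons[[1]]$sections[[1]])
  q_px <- unclass(truth[[1]][[1]])
  expect_equal(q_px, sweep(q_um, 2, origin) * 2.96 + 0.5, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("gaussian degradation has the stated moments and sigma = 0 is a no-op", {
  mid <- matrix(0.5, 300, 300)
  out <- degrade_image(mid, list(name = "gaussian", sigma = 40), seed = 3L)
  noise_sd <- stats::sd((out - mid) * 255)
  expect_lt(abs(noise_sd - 40) / 40, 0.05)
  out0 <- degrade_image(mid, list(name = "gaussian", sigma = 0), seed = 3L)
  expect_lt(max(abs(out0 - mid)), 1 / 250)  # 8-bit requantisation only
})

test_that("salt-and-pepper flips the requested pixel fraction to extremes", {
  mid <- matrix(0.5, 200, 200)
  out <- degrade_image(mid, list(name = "salt_pepper", fraction = 0.01), seed = 7L)
  flipped <- sum(out %in% c(0, 1))
  expect_equal(flipped, 400, tolerance = 0.1)
})

test_that("erase_corners paints every corner neighbourhood with background", {
  ov <- small_overview()
  truth <- attr(ov, "truth_px")
  dg <- degrade_image(ov, list(name = "erase_corners", k = 4, radius_px = 10),
                      truth_px = truth, seed = 2L)
  bg <- stats::quantile(ov$pixels, 0.9)
  for (q in truth[[1]]) for (i in 1:4) {
    v <- dg$pixels[round(q[i, 2]) + (-2:2), round(q[i, 1]) + (-2:2)]
    expect_lt(max(abs(v - bg)), 0.02)
  }
})

test_that("unknown degradation models raise a config error", {
  expect_error(degrade_image(matrix(0.5, 64, 64), list(name = "vignetting")),
               "config error")
})

test_that("the simulated microscope is deterministic and declares Fig-5 pixel sizes", {
  sc <- small_scene()
  expect_equal(mag_pixel_sizes()[["100x"]], 15.38)
  scope <- simulated_microscope(sc, stage_origin_um = c(0, 0), fov_px = 120)
  pos <- quad_centroid(sc$ribbons[[1]]$sections[[2]])
  scope$move_to(pos); scope$set_focus(0)
  f1 <- scope$acquire("100x")
  scope$move_to(pos)
  f2 <- scope$acquire("100x")
  expect_identical(unclass(f1)[, ], unclass(f2)[, ])
  expect_equal(attr(f1, "pixel_size"), 1 / 15.38)
  expect_error({ scope$move_to(c(1e6, 1e6)); scope$acquire("20x") }, "bounds")
})

test_that("acquiring at a true trajectory point centres the ROI structure", {
  sc <- small_scene()
  scope <- simulated_microscope(sc, stage_origin_um = c(0, 0), fov_px = 200)
  roi <- sc$rois[[1]]
  for (k in c(1, 3)) {
    scope$move_to(roi$trajectory[k, ])
    scope$set_focus(scene_focus_at(sc, roi$trajectory[k, 1], roi$trajectory[k, 2]))
    f <- scope$acquire("100x")
    # intensity-weighted centroid of the dark structure near the centre
    w <- pmax(stats::quantile(f, 0.2) - f, 0)
    w[-(60:140), ] <- 0; w[, -(60:140)] <- 0
    cx <- sum(col(f) * w) / sum(w); cy <- sum(row(f) * w) / sum(w)
    expect_lt(abs(cx - 100.5), 3)
    expect_lt(abs(cy - 100.5), 3)
  }
})

test_that("scenes and ground truth serialize and regenerate exactly", {
  sc <- small_scene()
  tf <- tempfile(fileext = ".json")
  write_scene(sc, tf)
  back <- read_scene(tf)
  expect_equal(back$ribbons, sc$ribbons, tolerance = 1e-12)
  expect_equal(back$rois[[1]]$trajectory, sc$rois[[1]]$trajectory)
  gt <- tempfile()
  export_ground_truth(sc, gt)
  secs <- utils::read.csv(file.path(gt, "sections.csv"))
  expect_equal(nrow(secs), sum(sc$section_counts) * 4)
  rois <- utils::read.csv(file.path(gt, "rois.csv"))
  expect_equal(nrow(rois), nrow(sc$rois[[1]]$trajectory))
})
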