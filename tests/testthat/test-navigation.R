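test_that("stage calibration maps the origin to (0,0) and 296 px to 100 um", {
  cal <- calibrate_stage(c(500, 700), 1 / 2.96)
  expect_equal(unname(px_to_stage(cal, c(500, 700))), c(0, 0))
  expect_equal(unname(px_to_stage(cal, c(500 + 296, 700))), c(100, 0),
               tolerance = 1e-9)
  # px -> stage -> px round trip
  set.seed(1)
  p <- matrix(stats::runif(20, 0, 2000), ncol = 2)
  expect_equal(stage_to_px(cal, px_to_stage(cal, p)), p,
               tolerance = 1e-9, ignore_attr = TRUE)
  # axis sign flips
  cal2 <- calibrate_stage(c(0, 0), 1, axis_signs = c(1, -1))
  expect_equal(unname(px_to_stage(cal2, c(10, 10))), c(10, -10))
})

make_toy_detection <- function(n = 5, pitch = c(0, 150)) {
  base <- rbind(c(100, 100), c(220, 100), c(212, 205), c(108, 205))
  quads <- lapply(seq_len(n), function(k)
    section_quad(base + matrix(pitch * (k - 1), 4, 2, byrow = TRUE)))
  structure(list(ribbons = list(ribbon(quads)),
                 scores = list(rep(1, n)), flags = list(vector("list", n))),
            class = "detection_result")
}

test_that("plans have one entry per ROI, section and magnification", {
  det <- make_toy_detection()
  cal <- calibrate_stage(c(100, 100), 1 / 2.96)
  roi <- define_roi("r1", det, 1, 1, c(160, 150))
  plan <- build_plan(roi, det, cal, NULL, mags = c("20x", "100x"),
                     start_section = 1, n_sections = 5)
  expect_equal(nrow(plan$entries), 10)
  expect_true(all(table(plan$entries$mag) == 5))
  expect_true(all(plan$entries$status == "pending"))
  expect_error(build_plan(roi, det, cal, NULL, mags = "20x",
                          start_section = 4, n_sections = 5), "range")
})

test_that("a centre ROI on a translated ribbon targets the section centroids", {
  det <- make_toy_detection()
  cal <- calibrate_stage(c(0, 0), 1)
  cen1 <- quad_centroid(det$ribbons[[1]]$sections[[1]])
  roi <- define_roi("r1", det, 1, 1, cen1)
  plan <- build_plan(roi, det, cal, NULL, mags = "20x", n_sections = 5)
  for (k in 1:5)
    expect_equal(c(plan$entries$x_um[k], plan$entries$y_um[k]),
                 unname(quad_centroid(det$ribbons[[1]]$sections[[k]])),
                 tolerance = 1e-6)
})

test_that("multi-ROI plans equal the concatenation of single-ROI plans", {
  det <- make_toy_detection()
  cal <- calibrate_stage(c(100, 100), 1 / 2.96)
  r1 <- define_roi("r1", det, 1, 1, c(160, 150))
  r2 <- define_roi("r2", det, 1, 2, c(140, 320))
  joint <- build_plan(list(r1, r2), det, cal, NULL, mags = "20x", n_sections = 5)
  solo1 <- build_plan(r1, det, cal, NULL, mags = "20x", n_sections = 5)
  solo2 <- build_plan(r2, det, cal, NULL, mags = "20x", n_sections = 5)
  expect_equal(joint$entries, rbind(solo1$entries, solo2$entries),
               ignore_attr = TRUE)
})

test_that("ROI natural coordinates are consistent with the inverse map and flag outsiders", {
  det <- make_toy_detection()
  roi <- define_roi("r1", det, 1, 2, c(160, 300))
  q <- det$ribbons[[1]]$sections[[2]]
  expect_equal(unname(forward_map(q, roi$natural)), c(160, 300), tolerance = 1e-7)
  expect_warning(define_roi("r2", det, 1, 1, c(400, 400)), "outside")
})

test_that("acquisition updates statuses, resumes, and tolerates entry failures", {
  sc <- small_scene()
  ov <- small_overview()
  det <- detect_all_sections(small_edge(), sketch_seeds(attr(ov, "truth_px")))
  origin_px <- unclass(det$ribbons[[1]]$sections[[1]])[1, ]
  cal <- calibrate_stage(origin_px, 1 / 2.96)
  so <- attr(ov, "origin_um") + (origin_px - 0.5) / 2.96
  cen <- quad_centroid(det$ribbons[[1]]$sections[[1]])
  roi <- define_roi("r1", det, 1, 1, cen + c(0, 5))
  plan <- build_plan(roi, det, cal, NULL, mags = "20x",
                     n_sections = length(det$ribbons[[1]]$sections))
  scope <- simulated_microscope(sc, so, fov_px = 96)
  pf <- tempfile(fileext = ".json")
  # interrupt after two entries: mark remaining done temporarily
  partial <- plan
  partial$entries$status[3:nrow(partial$entries)] <- "done"
  res1 <- acquire_stack(partial, scope, path = pf)
  expect_equal(sum(res1$plan$entries$status == "done"), nrow(plan$entries))
  expect_equal(length(res1$stacks[["r1/20x"]]$frames), 2)
  # resume: restore pending for the rest and acquire only those
  resumed <- res1$plan
  resumed$entries$status[3:nrow(plan$entries)] <- "pending"
  res2 <- acquire_stack(resumed, scope)
  expect_equal(length(res2$stacks[["r1/20x"]]$frames), nrow(plan$entries) - 2)
  # a plan with no pending entries is a no-op
  res3 <- acquire_stack(res2$plan, scope)
  expect_equal(length(res3$stacks), 0)
  # a failing scope marks entries failed and continues
  flaky <- scope
  n_call <- 0
  flaky$acquire <- function(mag) {
    n_call <<- n_call + 1
    if (n_call == 2) stop("beam blanked") else scope$acquire(mag)
  }
  expect_warning(res4 <- acquire_stack(plan, flaky), "failed")
  expect_equal(sum(res4$plan$entries$status == "failed"), 1)
  expect_equal(sum(res4$plan$entries$status == "done"), nrow(plan$entries) - 1)
})

test_that("navigation plans round-trip through JSON field for field", {
  det <- make_toy_detection()
  cal <- calibrate_stage(c(100, 100), 1 / 2.96, axis_signs = c(1, -1))
  focus <- focus_map(c(0, 50, 10), c(0, 5, 60), c(1.5, 2.25, -0.75))
  roi <- define_roi("r1", det, 1, 1, c(160, 150))
  plan <- build_plan(roi, det, cal, focus, mags = c("20x", "100x"), n_sections = 4)
  plan$entries$status[2] <- "done"; plan$entries$status[5] <- "failed"
  tf <- tempfile(fileext = ".json")
  write_plan(plan, tf)
  back <- roundtrip_plan(tf)
  expect_equal(back$entries, plan$entries)
  expect_equal(back$calibration$origin_px, cal$origin_px)
  expect_equal(back$calibration$axis_signs, cal$axis_signs)
  expect_equal(back$focus$z, focus$z)
  expect_equal(back$rois[[1]]$natural, roi$natural, tolerance = 1e-12)
  expect_equal(back$mag_table, plan$mag_table)
})

test_that("truncated plan files raise a parse error without a partial plan", {
  det <- make_toy_detection()
  cal <- calibrate_stage(c(100, 100), 1 / 2.96)
  roi <- define_roi("r1", det, 1, 1, c(160, 150))
  plan <- build_plan(roi, det, cal, NULL, mags = "20x", n_sections = 3)
  tf <- tempfile(fileext = ".json")
  write_plan(plan, tf)
  txt <- readChar(tf, file.size(tf))
  writeLines(substr(txt, 1, nchar(txt) %/% 2), tf)
  expect_error(roundtrip_plan(tf), "parse error")
  expect_error(roundtrip_plan(tempfile()), "does not exist")
})
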