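test_that("boundary error follows max-corner arithmetic", {
  q <- section_quad(rbind(c(0, 0), c(10, 0), c(9, 8), c(1, 8)))
  expect_equal(boundary_error(q, q, 1 / 2.96), 0)
  shifted <- section_quad(sweep(unclass(q), 2, c(3, 4), "+"))
  expect_equal(boundary_error(shifted, q, 1 / 2.96), 5 / 2.96, tolerance = 1e-12)
  # direct-enumeration oracle for random perturbations
  set.seed(13)
  for (i in 1:10) {
    pert <- matrix(stats::rnorm(8), 4, 2)
    qp <- section_quad(unclass(q) + pert, check = FALSE)
    oracle <- max(sqrt(pert[, 1]^2 + pert[, 2]^2))
    expect_equal(boundary_error(qp, q, 0.5), oracle * 0.5, tolerance = 1e-12)
  }
  expect_error(boundary_error(section_quad(unclass(q)[4:1, ], check = FALSE), q, 1),
               "convention")
})

test_that("an init already on the optimum barely moves", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  q <- truth[[1]][[2]]
  fit <- fit_active_contour(edge, q)
  expect_lt(max(sqrt(rowSums((unclass(fit) - unclass(q))^2))), 1.5)
})

test_that("a 20 px displaced init converges back to the section", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  q <- truth[[1]][[3]]
  init <- section_quad(unclass(q) + 20, check = FALSE)
  fit <- fit_active_contour(edge, init)
  expect_lt(max(sqrt(rowSums((unclass(fit) - unclass(q))^2))), 2)
})

test_that("fitting never increases the contour energy relative to the init", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  p <- detection_params()
  for (q in truth[[1]][2:3]) {
    init <- section_quad(unclass(q) + matrix(c(8, -6, 4, 5, -7, 3, 6, -4), 4, 2),
                         check = FALSE)
    fit <- fit_active_contour(edge, init)
    e_init <- -atnav:::perimeter_response(edge, unclass(init)) # shape dev of init is 0
    expect_lte(attr(fit, "energy"), e_init + 1e-9)
  }
})

test_that("an init fully outside the image raises an out-of-bounds error", {
  edge <- small_edge()
  far <- section_quad(rbind(c(1e5, 1e5), c(1e5 + 50, 1e5), c(1e5 + 50, 1e5 + 50),
                            c(1e5, 1e5 + 50)), check = FALSE)
  expect_error(fit_active_contour(edge, far), "out-of-bounds")
})

test_that("ribbon extension extrapolates pitch and corner drift", {
  q1 <- section_quad(rbind(c(0, 0), c(100, 0), c(95, 80), c(5, 80)))
  q2 <- section_quad(unclass(q1) + matrix(c(0, 0, 0, 0, 180, 180, 180, 180), 4, 2))
  edge <- matrix(0, 600, 300)
  pred <- extend_along_ribbon(edge, list(q1, q2))
  expect_equal(unclass(pred), unclass(q2) + (unclass(q2) - unclass(q1)),
               ignore_attr = TRUE)
  # shrinking sections: per-corner extrapolation tracks the shrink
  shrink <- function(q, f) {
    cen <- colMeans(q); sweep(sweep(q, 2, cen) * f, 2, cen + c(0, 90), "+")
  }
  qa <- unclass(q1); qb <- shrink(qa, 0.995)
  qc_true <- shrink(qb, 0.995)
  pred2 <- extend_along_ribbon(edge, list(section_quad(qa), section_quad(qb, check = FALSE)))
  expect_lt(max(sqrt(rowSums((unclass(pred2) - qc_true)^2))), 5)
  # a single section without a pitch vector is insufficient context
  expect_error(extend_along_ribbon(edge, list(q1)), "insufficient-context")
  pred3 <- extend_along_ribbon(edge, list(q1), pitch = c(0, 180))
  expect_equal(unclass(pred3), unclass(q1) + matrix(c(0, 0, 0, 0, 180, 180, 180, 180), 4, 2),
               ignore_attr = TRUE)
})

test_that("all sections of a noise-free layout are detected to subpixel accuracy", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  det <- detect_all_sections(edge, sketch_seeds(truth))
  expect_equal(n_sections(det), 10)
  errs <- matched_boundary_errors(det, truth, 1 / 2.96)
  expect_equal(length(errs), 10)
  expect_lt(max(errs) * 2.96, 2)  # < 2 px
})

test_that("detection is equivariant under global image translation", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  d <- c(40, 60)
  shifted <- matrix(0, nrow(edge) + d[2], ncol(edge) + d[1])
  shifted[d[2] + seq_len(nrow(edge)), d[1] + seq_len(ncol(edge))] <- edge
  seeds <- sketch_seeds(truth)
  seeds_s <- lapply(seeds, function(q) section_quad(sweep(unclass(q), 2, d, "+"),
                                                    check = FALSE))
  det1 <- detect_all_sections(edge, seeds[1])
  det2 <- detect_all_sections(structure(shifted, class = c("edge_map", "matrix")),
                              seeds_s[1])
  expect_equal(length(det1$ribbons[[1]]), length(det2$ribbons[[1]]))
  for (k in seq_along(det1$ribbons[[1]]$sections))
    expect_equal(unclass(det2$ribbons[[1]]$sections[[k]]),
                 unclass(det1$ribbons[[1]]$sections[[k]]) +
                   matrix(d, 4, 2, byrow = TRUE),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("detection survives erased corners and sides", {
  ov <- small_overview()
  truth <- attr(ov, "truth_px")
  for (model in list(list(name = "erase_corners", k = 4, radius_px = 12),
                     list(name = "erase_sides", k = 2, width_px = 5))) {
    dg <- degrade_image(ov, model, truth_px = truth, seed = 5L)
    edge <- preprocess_overview(dg)
    det <- detect_all_sections(edge, sketch_seeds(truth))
    mm <- match_detection(det, truth)
    expect_equal(sum(mm$matched), 10)
  }
})

test_that("detection results round-trip through JSON", {
  edge <- small_edge()
  truth <- attr(small_overview(), "truth_px")
  det <- detect_all_sections(edge, sketch_seeds(truth)[1])
  tf <- tempfile(fileext = ".json")
  write_detection(det, tf)
  back <- read_detection(tf)
  expect_equal(length(back$ribbons), length(det$ribbons))
  for (k in seq_along(det$ribbons[[1]]$sections))
    expect_equal(unclass(back$ribbons[[1]]$sections[[k]]),
                 unclass(det$ribbons[[1]]$sections[[k]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$scores[[1]], det$scores[[1]], tolerance = 1e-12)
})
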