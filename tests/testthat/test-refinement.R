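test_that("zero shifts leave the plan unchanged (idempotent refinement)", {
  ps <- make_plan_stack()
  reg0 <- reg_of(rep(0, 5), rep(0, 5))
  out <- refine_plan(ps$plan, reg0, ps$stack, next_mag = "100x")
  expect_equal(out$entries, ps$plan$entries)
  expect_true(all(attr(out, "corrections")$magnitude_um == 0))
})

test_that("refinement shifts only the target magnifications by shift times pixel size", {
  ps <- make_plan_stack()
  reg <- reg_of(c(0, 3, 6, 9, 12), c(0, -2, -4, -6, -8))
  out <- refine_plan(ps$plan, reg, ps$stack, next_mag = "100x",
                     smooth_window = 1L)
  e0 <- ps$plan$entries; e1 <- out$entries
  is20 <- e1$mag == "20x"
  expect_equal(e1$x_um[is20], e0$x_um[is20])  # below next_mag: untouched
  for (k in 1:5) {
    sel <- e1$mag == "100x" & e1$section == k
    expect_equal(e1$x_um[sel] - e0$x_um[sel], reg$dx_px[k] / 2.96,
                 tolerance = 1e-9)
    expect_equal(e1$y_um[sel] - e0$y_um[sel], reg$dy_px[k] / 2.96,
                 tolerance = 1e-9)
  }
})

test_that("corrections are additive across successive refinements", {
  ps <- make_plan_stack()
  r1 <- reg_of(c(0, 1, 2, 3, 4), c(0, 0.5, 1, 1.5, 2))
  r2 <- reg_of(c(0, -0.4, 0.2, 1, -1), c(0, 0.1, -0.3, 0.6, 0.9))
  seq_ref <- refine_plan(refine_plan(ps$plan, r1, ps$stack, "100x"),
                         r2, ps$stack, "100x")
  sum_reg <- reg_of(r1$dx_px + r2$dx_px, r1$dy_px + r2$dy_px)
  once <- refine_plan(ps$plan, sum_reg, ps$stack, "100x")
  expect_equal(seq_ref$entries, once$entries, tolerance = 1e-12)
})

test_that("axis signs flip the applied corrections", {
  ps <- make_plan_stack()
  ps$plan$calibration$axis_signs <- c(1, -1)
  reg <- reg_of(c(0, 2), c(0, 2))
  ps$stack$entries <- ps$stack$entries[1:2, ]
  ps$stack$frames <- ps$stack$frames[1:2]
  out <- refine_plan(ps$plan, reg, ps$stack, "100x", smooth_window = 1L)
  corr <- attr(out, "corrections")
  expect_equal(corr$dx_um[2], 2 / 2.96, tolerance = 1e-9)
  expect_equal(corr$dy_um[2], -2 / 2.96, tolerance = 1e-9)
})

test_that("frame/entry count mismatches raise a correspondence error", {
  ps <- make_plan_stack()
  expect_error(refine_plan(ps$plan, reg_of(c(0, 1), c(0, 1)), ps$stack, "100x"),
               "correspondence")
})

test_that("correction tables are written as the CSV twin of the error bookkeeping", {
  ps <- make_plan_stack()
  reg <- reg_of(c(0, 3, 6, 9, 12), c(0, -2, -4, -6, -8))
  out <- refine_plan(ps$plan, reg, ps$stack, next_mag = "100x")
  corr <- attr(out, "corrections")
  expect_equal(corr$magnitude_um, sqrt(corr$dx_um^2 + corr$dy_um^2))
  # the interior of a linear correction ramp is invariant under denoising
  expect_equal(corr$dx_um[2:4], c(3, 6, 9) / 2.96, tolerance = 1e-9)
  tf <- tempfile(fileext = ".csv")
  write_corrections(corr, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$magnitude_um, corr$magnitude_um, tolerance = 1e-12)
  expect_equal(names(back), c("section", "dx_um", "dy_um", "magnitude_um"))
})

test_that("the refinement loop repairs a deliberately corrupted plan", {
  # emulates coarse initial navigation: plan targets are perturbed by a
  # systematic offset plus noise, then one 20x register/refine round must
  # bring the ROI back near the frame centres
  res <- run_pipeline(list(
    seed = 5L,
    scene = list(n_ribbons = 1L, sections_total = 8L,
                 sections_range = c(8L, 8L)),
    rois = list(anchor_section = 1L),
    navigation = list(n_sections = 8L),
    microscope = list(jitter_um = 0.2)), out_dir = tempfile())
  sc <- res$scene
  tru <- sweep(sc$rois[[1]]$trajectory, 2, res$stage_origin_um)
  plan <- res$plan_initial
  sel20 <- plan$entries$mag == "20x"
  offsets <- cbind(5 + seq(0, 2.1, length.out = 8), -4 + seq(0, 1.4, length.out = 8))
  offsets[1, ] <- 0   # the anchor section stays where the user clicked
  plan$entries$x_um[sel20] <- plan$entries$x_um[sel20] + offsets[, 1]
  plan$entries$y_um[sel20] <- plan$entries$y_um[sel20] + offsets[, 2]
  plan$entries$x_um[!sel20] <- plan$entries$x_um[!sel20] + offsets[, 1]
  plan$entries$y_um[!sel20] <- plan$entries$y_um[!sel20] + offsets[, 2]
  scope <- simulated_microscope(sc, res$stage_origin_um, fov_px = 200,
                                jitter_um = 0.2, seed = 99L)
  acq <- acquire_stack(plan, scope, mag = "20x")
  stk <- acq$stacks[[1]]
  reg <- register_stack(stk, reference = 1L)
  refined <- refine_plan(acq$plan, reg, stk, next_mag = "100x")
  e100 <- refined$entries[refined$entries$mag == "100x", ]
  err_before <- sqrt(rowSums((offsets)^2))
  err_after <- sqrt((e100$x_um - tru[, 1])^2 + (e100$y_um - tru[, 2])^2)
  expect_lt(stats::median(err_after), stats::median(err_before))
  expect_lt(max(err_after[-1]), 3)
})
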