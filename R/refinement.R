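#' Register an acquired image stack
#'
#' Chained pairwise registration: each frame is phase-correlated against
#' its predecessor (neighbouring sections are the most similar, since
#' structures change shape along the ribbon), shifts are accumulated to a
#' reference frame, and the accumulated shift of the reference frame is
#' zero.  Subpixel estimation uses Fourier upsampling to 0.1 px.
#' `mode = "rigid"` adds a coarse rotation search (+-5 deg, 0.5 deg steps)
#' per pair; rotations are reported but only translations feed back into
#' the navigation plan.
#'
#' @param stack an `image_stack` (or plain list of matrices).
#' @param mode `"translation"` or `"rigid"`.
#' @param reference index of the reference frame (shift fixed to 0).
#' @param min_confidence pairs below this peak ratio contribute zero shift
#'   and flag the frame as low confidence.
#' @param max_shift_frac pairwise shifts larger than this fraction of the
#'   frame size are implausible for consecutive serial sections (typically
#'   a wrap-around alias) and are treated as failed pairs (zero shift, low
#'   confidence).
#' @return a `registration_result`: data frame (frame, dx_px, dy_px,
#'   rotation_deg, confidence, low_confidence) with attribute `reference`.
#' @export
register_stack <- function(stack, mode = c("translation", "rigid"),
                           reference = 1L, min_confidence = 0.15,
                           max_shift_frac = 0.25) {
  mode <- match.arg(mode)
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  n <- length(frames)
  stopifnot(n >= 2, reference >= 1, reference <= n)
  d <- matrix(0, n, 2); rot <- numeric(n); conf <- rep(Inf, n)
  for (k in 2:n) {
    a <- frames[[k - 1]]; b <- frames[[k]]
    th <- 0
    if (mode == "rigid") {
      best <- -Inf
      for (cand in seq(-5, 5, by = 0.5)) {
        br <- if (abs(cand) < 1e-9) b else
          as_mat(EBImage::rotate(b, cand, output.dim = dim(b)[c(2, 1)]))
        pc <- phase_correlate(a, br, upsample = 1)
        if (pc$confidence > best) { best <- pc$confidence; th <- cand }
      }
      if (abs(th) > 1e-9)
        b <- as_mat(EBImage::rotate(b, th, output.dim = dim(b)[c(2, 1)]))
    }
    pc <- phase_correlate(a, b, upsample = 10)
    s <- pc$shift
    if (pc$confidence < min_confidence ||
        any(abs(s) > max_shift_frac * dim(a)[c(2, 1)])) {
      s <- c(dx = 0, dy = 0)
      pc$confidence <- 0
    }
    d[k, ] <- d[k - 1, ] + s
    rot[k] <- rot[k - 1] + th
    conf[k] <- pc$confidence
  }
  d <- sweep(d, 2, d[reference, ])
  rot <- rot - rot[reference]
  out <- data.frame(frame = seq_len(n), dx_px = d[, 1], dy_px = d[, 2],
                    rotation_deg = rot, confidence = conf,
                    low_confidence = conf < min_confidence)
  structure(out, class = c("registration_result", "data.frame"),
            reference = reference, mode = mode)
}

#' Feed registration shifts back into the navigation plan
#'
#' The stepwise-refinement feedback: the shift each frame needed during
#' stack registration measures how far the acquired ROI sat from its
#' predicted position, so adding it (converted to stage micrometres) to
#' the per-section targets corrects the navigation for the next, higher
#' magnification.  Only entries of the registered ROI at magnifications at
#' or above `next_mag` on the ladder are updated.  Per-section corrections
#' are recorded as `(dx_um, dy_um, sqrt(dx^2 + dy^2))`.
#'
#' The navigation-error field varies smoothly along a ribbon (propagation
#' error and ROI drift change gradually from section to section) while
#' stage repeatability error is independent per frame, so the measured
#' corrections are denoised with a short centered running mean before
#' being applied (`smooth_window`, default 3 sections; 1 disables).
#'
#' @param plan a `navigation_plan`.
#' @param reg a `registration_result` whose frames correspond 1:1 to the
#'   plan entries in `stack` (one ROI, one magnification, section order).
#' @param stack the registered `image_stack` (supplies pixel size and the
#'   entry provenance).
#' @param next_mag magnification label whose entries (and all higher) get
#'   the correction.
#' @param stack_pixel_size um/px of the registered stack; defaults to the
#'   stack's own value.
#' @param smooth_window odd window (sections) of the running-mean denoising
#'   of the correction field; 1 applies the raw per-section shifts.
#' @return updated `navigation_plan`; attribute `corrections` holds the
#'   per-section correction table (section, dx_um, dy_um, magnitude_um) as
#'   applied.
#' @export
refine_plan <- function(plan, reg, stack, next_mag,
                        stack_pixel_size = stack$pixel_size,
                        smooth_window = 3L) {
  se <- stack$entries
  if (nrow(reg) != nrow(se))
    stop("correspondence error: registration frames != stack entries")
  signs <- plan$calibration$axis_signs
  dx_um <- signs[1] * reg$dx_px * stack_pixel_size
  dy_um <- signs[2] * reg$dy_px * stack_pixel_size
  dx_um <- running_mean(dx_um, smooth_window)
  dy_um <- running_mean(dy_um, smooth_window)
  corr <- data.frame(section = se$section, dx_um = dx_um, dy_um = dy_um,
                     magnitude_um = sqrt(dx_um^2 + dy_um^2))
  ladder <- plan$mag_table
  if (!next_mag %in% names(ladder))
    stop(sprintf("unknown magnification '%s'", next_mag))
  target_mags <- names(ladder)[ladder >= ladder[[next_mag]]]
  e <- plan$entries
  roi <- se$roi_id[1]
  for (i in seq_len(nrow(corr))) {
    sel <- e$roi_id == roi & e$section == corr$section[i] & e$mag %in% target_mags
    e$x_um[sel] <- e$x_um[sel] + corr$dx_um[i]
    e$y_um[sel] <- e$y_um[sel] + corr$dy_um[i]
  }
  plan$entries <- e
  attr(plan, "corrections") <- corr
  plan
}

# centered running mean with edge truncation
running_mean <- function(x, window) {
  if (window <= 1 || length(x) < 3) return(x)
  h <- (window - 1) %/% 2
  vapply(seq_along(x), function(i)
    mean(x[max(1, i - h):min(length(x), i + h)]), numeric(1))
}

#' Write a per-section correction table as CSV
#'
#' The machine-readable record of how much the refinement moved each
#' section's target: columns section, dx_um, dy_um, magnitude_um.
#'
#' @param corrections data frame as attached by [refine_plan()].
#' @param path CSV file path.
#' @export
write_corrections <- function(corrections, path) {
  utils::write.csv(corrections, path, row.names = FALSE)
  invisible(path)
}

#' Correction magnitude bookkeeping
#'
#' Combines per-axis corrections into the reported error magnitude
#' `sqrt(dx^2 + dy^2)` in micrometres.
#'
#' @param dx_um,dy_um per-axis corrections (um).
#' @export
correction_magnitude <- function(dx_um, dy_um) sqrt(dx_um^2 + dy_um^2)
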