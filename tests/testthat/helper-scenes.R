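# lazily built, cached fixtures shared across test files; everything is
# generated in code from seeded parameters
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_scene <- function() fixture("small_scene", function()
  generate_scene(list(n_ribbons = 2L, sections_total = 10L,
                      sections_range = c(4L, 6L)), seed = 3L))

small_overview <- function() fixture("small_overview", function()
  render_overview(small_scene(), 2.96))

small_edge <- function() fixture("small_edge", function()
  preprocess_overview(small_overview()))

# a deterministic "user sketch": the true middle-section quad, jittered
sketch_seeds <- function(truth_px, seed = 9L, amp = 3) {
  atnav:::with_seed(seed, lapply(truth_px, function(rb) {
    k <- ceiling(length(rb) / 2)
    section_quad(unclass(rb[[k]]) + matrix(stats::runif(8, -amp, amp), 4, 2),
                 check = FALSE)
  }))
}

# boundary error of every matched section against ground truth, um
matched_boundary_errors <- function(det, truth_px, pixel_size) {
  mm <- match_detection(det, truth_px)
  vapply(which(mm$matched), function(i) {
    tq <- truth_px[[mm$truth_ribbon[i]]][[mm$truth_index[i]]]
    dq <- det$ribbons[[mm$ribbon[i]]]$sections[[mm$det_index[i]]]
    boundary_error(align_corners(dq, tq), tq, pixel_size)
  }, numeric(1))
}

random_convex_quad <- function() {
  repeat {
    ang <- sort(stats::runif(4, 0, 2 * pi))
    if (min(diff(c(ang, ang[1] + 2 * pi))) < 0.3) next
    r <- stats::runif(4, 4, 10)
    q <- cbind(10 + r * cos(ang), 10 + r * sin(ang))
    q <- q[order(atan2(q[, 2] - mean(q[, 2]), q[, 1] - mean(q[, 1]))), ]
    if (quad_area(q) < 0) q <- q[4:1, ]
    if (is_convex_quad(q) && quad_area(q) > 5) return(section_quad(q))
  }
}

# a toy navigation plan over a straight ribbon, with a matching 20x stack
# shell whose frames are placeholders (used by refinement bookkeeping tests)
make_plan_stack <- function(n = 5, mags = c("20x", "100x")) {
  base <- rbind(c(100, 100), c(220, 100), c(212, 205), c(108, 205))
  quads <- lapply(seq_len(n), function(k)
    section_quad(base + matrix(c(0, 150) * (k - 1), 4, 2, byrow = TRUE)))
  det <- structure(list(ribbons = list(ribbon(quads)),
                        scores = list(rep(1, n)), flags = list(vector("list", n))),
                   class = "detection_result")
  cal <- calibrate_stage(c(100, 100), 1 / 2.96)
  roi <- define_roi("r1", det, 1, 1, c(160, 150))
  plan <- build_plan(roi, det, cal, NULL, mags = mags, n_sections = n)
  entries20 <- plan$entries[plan$entries$mag == "20x", ]
  rownames(entries20) <- NULL
  stack <- structure(list(frames = replicate(n, matrix(0, 8, 8), simplify = FALSE),
                          entries = entries20, pixel_size = 1 / 2.96,
                          settle_s = 2), class = "image_stack")
  list(plan = plan, stack = stack)
}

reg_of <- function(dx_px, dy_px) {
  n <- length(dx_px)
  structure(data.frame(frame = seq_len(n), dx_px = dx_px, dy_px = dy_px,
                       rotation_deg = 0, confidence = 10,
                       low_confidence = FALSE),
            class = c("registration_result", "data.frame"),
            reference = 1L, mode = "translation")
}

# pixels that are 3x3-neighbourhood maxima of a positive response map
as_local_maxima <- function(edge) {
  dil <- EBImage::imageData(EBImage::dilate(unclass(edge),
                                            EBImage::makeBrush(3, "box")))
  unclass(edge) >= dil - 1e-12 & unclass(edge) > 0.05 * max(edge)
}

roll_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}
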