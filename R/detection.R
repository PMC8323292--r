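#' Default detection parameters
#'
#' @return list: `search_radius` (px, per-corner search extent),
#'   `lambda_shape` (weight of the shape prior against the edge term),
#'   `levels` (image-pyramid downscale factors, coarse to fine),
#'   `max_iter` (greedy iterations per level), `reject_frac` (a section is
#'   accepted while its fit score stays above this fraction of the seed
#'   section's score), `min_area_frac` (fits shrinking below this fraction
#'   of the init area are rejected), `max_sections` (per-direction cap).
#' @export
detection_params <- function() {
  list(search_radius = 20, lambda_shape = 0.3, levels = c(4, 2, 1),
       max_iter = 60, reject_frac = 0.4, min_area_frac = 0.25,
       max_sections = 200L)
}

# mean edge response sampled along the quad perimeter (bilinear)
perimeter_response <- function(edge, quad, n_per_edge = NULL) {
  nn <- c(2, 3, 4, 1)
  xs <- NULL; ys <- NULL
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[nn[i], ]
    len <- sqrt(sum((b - a)^2))
    n <- if (is.null(n_per_edge)) max(6L, ceiling(len / 2)) else n_per_edge
    t <- (seq_len(n) - 0.5) / n
    xs <- c(xs, a[1] + t * (b[1] - a[1]))
    ys <- c(ys, a[2] + t * (b[2] - a[2]))
  }
  mean(bilinear_sample(edge, xs, ys))
}

bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  ix0 <- cl(x0, nc); ix1 <- cl(x0 + 1, nc)
  iy0 <- cl(y0, nr); iy1 <- cl(y0 + 1, nr)
  out_of <- x < 0.5 | x > nc + 0.5 | y < 0.5 | y > nr + 0.5
  v <- img[cbind(iy0, ix0)] * (1 - fx) * (1 - fy) +
       img[cbind(iy0, ix1)] * fx * (1 - fy) +
       img[cbind(iy1, ix0)] * (1 - fx) * fy +
       img[cbind(iy1, ix1)] * fx * fy
  v[out_of] <- 0
  v
}

quad_side_lengths <- function(quad) {
  nn <- c(2, 3, 4, 1)
  sqrt(rowSums((quad[nn, ] - quad)^2))
}

quad_angles <- function(quad) {
  prv <- c(4, 1, 2, 3); nn <- c(2, 3, 4, 1)
  a <- quad[prv, ] - quad; b <- quad[nn, ] - quad
  ang <- atan2(a[, 2], a[, 1]) - atan2(b[, 2], b[, 1])
  abs(((ang + pi) %% (2 * pi)) - pi)
}

shape_deviation <- function(quad, ref_len, ref_ang) {
  len <- quad_side_lengths(quad)
  ang <- quad_angles(quad)
  mean(abs(len - ref_len) / ref_len) + mean(abs(ang - ref_ang)) / (pi / 2)
}

#' Fit a quadrilateral active contour to the edge map
#'
#' Deforms an initial quadrilateral to maximise the mean edge response
#' along its perimeter while a shape prior keeps side lengths and corner
#' angles close to the init.  The energy
#' `E = -(mean perimeter edge response) + lambda_shape * shape deviation`
#' is minimised by coordinate-wise greedy search over the four corners,
#' whole-quad and side translations (1 px steps, ties broken toward the
#' smallest displacement from the init), inside a 3-level image pyramid.
#' The result never has higher full-resolution energy than the init.
#'
#' @param edge an `edge_map` (matrix; boundaries are maxima).
#' @param init initial `section_quad` in edge-map pixel coordinates.
#' @param params see [detection_params()].
#' @return fitted `section_quad` with attributes `score` (mean perimeter
#'   edge response at full resolution), `energy`, and `flags` (character:
#'   may contain "degenerate" or "non_convex").
#' @export
fit_active_contour <- function(edge, init, params = detection_params()) {
  p <- utils::modifyList(detection_params(), params)
  init <- as_quad(init)
  nr <- nrow(edge); nc <- ncol(edge)
  if (max(init[, 1]) < 1 || min(init[, 1]) > nc ||
      max(init[, 2]) < 1 || min(init[, 2]) > nr)
    stop("out-of-bounds: init quadrilateral lies fully outside the image")
  margin <- 2 * p$search_radius + 24
  jx <- max(1, floor(min(init[, 1]) - margin)):min(nc, ceiling(max(init[, 1]) + margin))
  iy <- max(1, floor(min(init[, 2]) - margin)):min(nr, ceiling(max(init[, 2]) + margin))
  crop <- edge[iy, jx, drop = FALSE]
  off <- c(jx[1] - 1, iy[1] - 1)
  q <- sweep(unclass(init), 2, off)
  q0 <- q
  for (f in p$levels) {
    lev <- if (f == 1) crop else
      as_mat(EBImage::gblur(
        EBImage::resize(crop, w = max(8, round(nrow(crop) / f)),
                        h = max(8, round(ncol(crop) / f))), sigma = 1))
    ql <- (q - 0.5) / f + 0.5
    q0l <- (q0 - 0.5) / f + 0.5
    ql <- greedy_refine(lev, ql, q0l, p, radius = max(2, ceiling(p$search_radius / f)))
    q <- (ql - 0.5) * f + 0.5
  }
  # monotone guarantee: keep the init if refinement did not lower the energy
  ref_len <- quad_side_lengths(q0); ref_ang <- quad_angles(q0)
  energy_of <- function(qq) -perimeter_response(crop, qq) +
    p$lambda_shape * shape_deviation(qq, ref_len, ref_ang)
  if (energy_of(q) > energy_of(q0)) q <- q0
  flags <- character(0)
  if (abs(quad_area(q)) < p$min_area_frac * abs(quad_area(q0))) {
    q <- q0; flags <- c(flags, "degenerate")
  }
  out <- sweep(q, 2, off, "+")
  score <- perimeter_response(edge, out)
  if (!is_convex_quad(out)) flags <- c(flags, "non_convex")
  structure(section_quad(out, check = FALSE),
            score = score, energy = energy_of(q), flags = flags)
}

greedy_refine <- function(lev, q, q0, p, radius) {
  ref_len <- quad_side_lengths(q0); ref_ang <- quad_angles(q0)
  energy <- function(qq) -perimeter_response(lev, qq) +
    p$lambda_shape * shape_deviation(qq, ref_len, ref_ang)
  e <- energy(q)
  steps <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  nn <- c(2, 3, 4, 1)
  for (iter in seq_len(p$max_iter)) {
    best <- NULL; best_e <- e; best_disp <- Inf
    try_cand <- function(qq) {
      if (quad_area(qq) <= 0) return()
      if (max(abs(qq - q0)) > radius * 2.5) return()
      ee <- energy(qq)
      disp <- sum((qq - q0)^2)
      if (ee < best_e - 1e-12 ||
          (ee < best_e + 1e-12 && !is.null(best) && disp < best_disp)) {
        best <<- qq; best_e <<- ee; best_disp <<- disp
      }
    }
    for (s in seq_len(nrow(steps))) {
      d <- steps[s, ]
      for (ci in 1:4) { qq <- q; qq[ci, ] <- qq[ci, ] + d; try_cand(qq) }
      try_cand(sweep(q, 2, d, "+"))                       # whole quad
      for (si in 1:4) {                                   # side handles
        qq <- q; qq[c(si, nn[si]), ] <- sweep(qq[c(si, nn[si]), ], 2, d, "+")
        try_cand(qq)
      }
    }
    if (is.null(best)) break
    q <- best; e <- best_e
  }
  q
}

#' Predict the next section's initial quadrilateral along a ribbon
#'
#' With two or more detected sections, the init for the next section is
#' the last quadrilateral translated by the last inter-section centroid
#' vector with per-corner extrapolation of the observed corner drift (so
#' gradual shrinking and shearing are carried forward).  With exactly one
#' section the ribbon pitch cannot be inferred and a user-supplied pitch
#' vector is required.
#'
#' @param edge the edge map (used only for bounds information).
#' @param detected list of `section_quad` in cutting order.
#' @param pitch optional `c(dx, dy)` pitch vector (px), required when only
#'   one section has been detected.
#' @return predicted `section_quad` init.
#' @export
extend_along_ribbon <- function(edge, detected, pitch = NULL) {
  n <- length(detected)
  stopifnot(n >= 1)
  if (n == 1) {
    if (is.null(pitch))
      stop("insufficient-context: one detected section and no pitch vector")
    return(section_quad(sweep(unclass(as_quad(detected[[1]])), 2, pitch, "+"),
                        check = FALSE))
  }
  q1 <- unclass(as_quad(detected[[n - 1]]))
  q2 <- unclass(as_quad(detected[[n]]))
  drift <- q2 - q1   # per-corner: centroid pitch + shape drift
  section_quad(q2 + drift, check = FALSE)
}

#' Detect every section of every ribbon from one seed per ribbon
#'
#' For each seed the section is fitted, then detection alternates
#' [extend_along_ribbon()] and [fit_active_contour()] in both directions
#' from the seed until the fit score drops below `reject_frac` times the
#' seed score, the predicted init leaves the image, or the contour stops
#' advancing.  Corner ordering is canonicalised on the seed and inherited
#' by every fit, so one convention holds across each ribbon.
#'
#' @param edge an `edge_map`.
#' @param seeds list of one seed `section_quad` per ribbon (user sketches).
#' @param params see [detection_params()].
#' @return a `detection_result`: list with `ribbons` (list of `at_ribbon`
#'   in cutting order), `scores` and `flags` (parallel lists).
#' @export
detect_all_sections <- function(edge, seeds, params = detection_params()) {
  p <- utils::modifyList(detection_params(), params)
  if (inherits(seeds, "section_quad")) seeds <- list(seeds)
  stopifnot(length(seeds) >= 1)
  ribbons <- list(); scores <- list(); flags <- list()
  for (seed in seeds) {
    seed <- order_corners(unclass(as_quad(seed)))
    fit0 <- fit_active_contour(edge, seed, p)
    s0 <- attr(fit0, "score")
    if (!length(s0) || s0 <= 0) next  # seed fit failed: empty ribbon result
    thr <- p$reject_frac * s0
    # pitch estimate from the seed itself: leading-edge midpoint to
    # trailing-edge midpoint is one section step along the ribbon axis
    q0 <- unclass(fit0)
    pitch0 <- (q0[3, ] + q0[4, ]) / 2 - (q0[1, ] + q0[2, ]) / 2
    walk <- function(dir_sign) {
      cur <- list(fit0)
      res <- list(quads = list(), scores = numeric(0), flags = list())
      repeat {
        if (length(res$quads) >= p$max_sections) break
        init <- if (length(cur) == 1) {
          # the seed quad's own height underestimates the pitch by the seam
          # width, so scan the perimeter response along the ribbon axis for
          # the best-supported first step
          base <- unclass(as_quad(cur[[1]]))
          scales <- seq(0.85, 1.45, by = 0.01)
          resp <- vapply(scales, function(s)
            perimeter_response(edge, base + matrix(dir_sign * s * pitch0,
                                                   4, 2, byrow = TRUE),
                               n_per_edge = 12L), numeric(1))
          extend_along_ribbon(edge, cur,
                              pitch = dir_sign * scales[which.max(resp)] * pitch0)
        } else extend_along_ribbon(edge, cur)
        cen <- quad_centroid(init)
        if (cen[1] < 1 || cen[1] > ncol(edge) || cen[2] < 1 || cen[2] > nrow(edge))
          break
        fit <- tryCatch(fit_active_contour(edge, init, p), error = function(e) NULL)
        if (is.null(fit) || attr(fit, "score") < thr) break
        if ("degenerate" %in% attr(fit, "flags")) break
        move <- sqrt(sum((quad_centroid(fit) - quad_centroid(cur[[length(cur)]]))^2))
        pitch <- sqrt(sum((quad_centroid(init) - quad_centroid(cur[[length(cur)]]))^2))
        if (move < 0.4 * pitch || move > 1.8 * pitch) break
        res$quads[[length(res$quads) + 1]] <- fit
        res$scores <- c(res$scores, attr(fit, "score"))
        res$flags[[length(res$flags) + 1]] <- attr(fit, "flags")
        cur <- c(cur, list(fit))
      }
      res
    }
    fwd <- walk(+1)
    bwd <- walk(-1)
    quads <- c(rev(bwd$quads), list(fit0), fwd$quads)
    sc <- c(rev(bwd$scores), s0, fwd$scores)
    fl <- c(rev(bwd$flags), list(attr(fit0, "flags")), fwd$flags)
    ribbons[[length(ribbons) + 1]] <- ribbon(lapply(quads, function(q)
      section_quad(unclass(q), check = FALSE)))
    scores[[length(scores) + 1]] <- sc
    flags[[length(flags) + 1]] <- fl
  }
  structure(list(ribbons = ribbons, scores = scores, flags = flags),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d ribbon(s), %s sections\n",
              length(x$ribbons),
              paste(vapply(x$ribbons, length, integer(1)), collapse = "+")))
  invisible(x)
}

#' Total number of detected sections
#' @param det a `detection_result`.
#' @export
n_sections <- function(det) sum(vapply(det$ribbons, length, integer(1)))

#' Boundary localisation error between a detected and a true section
#'
#' The maximum over the four corners of the Euclidean distance to the
#' corresponding true corner, converted to micrometres.
#'
#' @param detected,truth `section_quad`s under the same corner-ordering
#'   convention.
#' @param pixel_size micrometres per pixel.
#' @return error in micrometres.
#' @export
boundary_error <- function(detected, truth, pixel_size) {
  d <- unclass(as_quad(detected)); t <- unclass(as_quad(truth))
  if (sign(quad_area(d)) != sign(quad_area(t)))
    stop("corner-ordering convention mismatch (reversed orientation)")
  max(sqrt(rowSums((d - t)^2))) * pixel_size
}

#' Serialize / restore a detection result as JSON
#' @param det a `detection_result`.
#' @param path output file.
#' @export
write_detection <- function(det, path) {
  obj <- list(ribbons = lapply(seq_along(det$ribbons), function(r) list(
    sections = lapply(det$ribbons[[r]]$sections, function(q)
      as.vector(t(unclass(q)))),   # x1,y1,x2,y2,...
    scores = as.numeric(det$scores[[r]]),
    flags = lapply(det$flags[[r]], as.character))))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_detection
#' @export
read_detection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ribbons <- list(); scores <- list(); flags <- list()
  for (r in seq_along(obj$ribbons)) {
    rb <- obj$ribbons[[r]]
    qs <- lapply(rb$sections, function(v)
      section_quad(matrix(unlist(v), 4, 2, byrow = TRUE), check = FALSE))
    ribbons[[r]] <- ribbon(qs)
    scores[[r]] <- unlist(rb$scores)
    flags[[r]] <- lapply(rb$flags, unlist)
  }
  structure(list(ribbons = ribbons, scores = scores, flags = flags),
            class = "detection_result")
}
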