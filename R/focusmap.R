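#' Create a focus map from manual focus anchors
#'
#' During overview acquisition the user focuses the microscope at a handful
#' of stage positions in every ribbon; the resulting (x, y, z) anchors
#' define a focus surface that is queried for every planned acquisition at
#' the light-microscope level.
#'
#' @param x,y anchor stage positions (micrometres).
#' @param z focus values at the anchors (micrometres).
#' @return a `focus_map` object.
#' @export
focus_map <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z), length(x) >= 1,
            all(is.finite(c(x, y, z))))
  d <- as.matrix(stats::dist(cbind(x, y)))
  if (length(x) > 1 && min(d[upper.tri(d)]) < 1e-9)
    stop("duplicate anchor positions")
  structure(list(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            class = "focus_map")
}

#' @export
print.focus_map <- function(x, ...) {
  cat(sprintf("focus_map: %d anchors, z in [%.2f, %.2f] um\n",
              length(x$x), min(x$z), max(x$z)))
  invisible(x)
}

#' Interpolate the focus surface
#'
#' Inside the convex hull of the anchors the surface is evaluated by Sibson
#' natural-neighbour interpolation, computed exactly: the Voronoi cell that
#' a query point would acquire on insertion is intersected with each
#' anchor's cell by half-plane clipping, and the stolen areas form the
#' interpolation weights.  The interpolant is exact at anchors and has
#' linear precision.  Outside the hull (or with fewer than three
#' non-collinear anchors) the nearest anchor's focus is returned and the
#' query is flagged as extrapolated.
#'
#' @param map a `focus_map`.
#' @param x,y query stage position(s) in micrometres.
#' @return numeric z (micrometres), with attribute `extrapolated` (logical).
#' @export
interpolate_focus <- function(map, x, y) {
  stopifnot(inherits(map, "focus_map"), length(x) == length(y))
  n <- length(map$x)
  anchors <- cbind(map$x, map$y)
  degenerate <- n < 3 || is_collinear(anchors)
  hull <- if (!degenerate) anchors[grDevices::chull(anchors), , drop = FALSE]
  z <- numeric(length(x)); extra <- logical(length(x))
  for (i in seq_along(x)) {
    p <- c(x[i], y[i])
    d2 <- (map$x - p[1])^2 + (map$y - p[2])^2
    if (min(d2) < 1e-18) { z[i] <- map$z[which.min(d2)]; next }
    if (degenerate || !point_in_convex_poly(p, hull)) {
      z[i] <- map$z[which.min(d2)]
      extra[i] <- TRUE
      next
    }
    w <- sibson_weights(anchors, p)
    z[i] <- sum(w * map$z)
  }
  structure(z, extrapolated = extra)
}

is_collinear <- function(pts) {
  if (nrow(pts) < 3) return(TRUE)
  p0 <- pts[1, ]
  v <- sweep(pts[-1, , drop = FALSE], 2, p0)
  cr <- abs(v[1, 1] * v[-1, 2] - v[1, 2] * v[-1, 1])
  scale <- max(abs(v)) ^ 2 + 1e-30
  all(cr / scale < 1e-10)
}

point_in_convex_poly <- function(p, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  cr <- (poly[j, 1] - poly[, 1]) * (p[2] - poly[, 2]) -
        (poly[j, 2] - poly[, 2]) * (p[1] - poly[, 1])
  all(cr >= -tol * (max(abs(poly)) + 1)) || all(cr <= tol * (max(abs(poly)) + 1))
}

# clip a convex polygon to the half-plane { q : dot(q - m, nrm) <= 0 }
clip_halfplane <- function(poly, m, nrm) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  s <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2]
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a_in <- s[i] <= 0; b_in <- s[j] <= 0
    if (a_in) out <- rbind(out, poly[i, ])
    if (xor(a_in, b_in)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

poly_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# exact Sibson weights for a query strictly inside the anchor hull
sibson_weights <- function(anchors, p) {
  n <- nrow(anchors)
  span <- max(diff(range(anchors[, 1])), diff(range(anchors[, 2])), 1)
  r <- 10 * span
  box <- cbind(p[1] + c(-r, r, r, -r), p[2] + c(-r, -r, r, r))
  # Voronoi cell of p after insertion into the anchor set
  cell <- box
  for (k in seq_len(n)) {
    s <- anchors[k, ]
    cell <- clip_halfplane(cell, (p + s) / 2, s - p)
    if (nrow(cell) == 0) break
  }
  w <- numeric(n)
  if (nrow(cell) < 3) return(w)  # degenerate; caller handles via exactness check
  for (k in seq_len(n)) {
    piece <- cell
    for (j in seq_len(n)) {
      if (j == k) next
      piece <- clip_halfplane(piece, (anchors[k, ] + anchors[j, ]) / 2,
                              anchors[j, ] - anchors[k, ])
      if (nrow(piece) == 0) break
    }
    w[k] <- poly_area(piece)
  }
  w / sum(w)
}
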