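#' Construct a section quadrilateral
#'
#' A section is represented by its four corners in a fixed cyclic order:
#' counter-clockwise in image coordinates (x right, y down), starting from
#' the corner nearest the ribbon's leading (first-cut) edge.  With that
#' convention the shoelace signed area is strictly positive.
#'
#' @param corners numeric 4x2 matrix (columns x, y) or length-8 vector
#'   (x1, y1, x2, y2, ...).
#' @param check validate invariants (simple polygon, positive area,
#'   distinct corners).
#' @return a `section_quad`: a 4x2 matrix with columns `x`, `y`.
#' @export
section_quad <- function(corners, check = TRUE) {
  if (is.vector(corners)) corners <- matrix(corners, ncol = 2, byrow = TRUE)
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4, 2)) || !is.numeric(corners))
    stop("invalid-geometry: corners must be a 4x2 numeric matrix")
  dimnames(corners) <- list(NULL, c("x", "y"))
  if (check) {
    if (!all(is.finite(corners)))
      stop("invalid-geometry: non-finite corner coordinates")
    d <- as.matrix(stats::dist(corners))
    if (min(d[upper.tri(d)]) < 1e-9)
      stop("invalid-geometry: coincident corners")
    if (quad_area(corners) <= 0)
      stop("invalid-geometry: corner order must give positive signed area")
    if (!is_simple_quad(corners))
      stop("invalid-geometry: self-intersecting quadrilateral")
  }
  class(corners) <- c("section_quad", class(corners))
  corners
}

#' Shoelace signed area of a quadrilateral
#' @param quad 4x2 corner matrix.
#' @return signed area (positive for the package's corner convention).
#' @export
quad_area <- function(quad) {
  x <- quad[, 1]; y <- quad[, 2]
  j <- c(2, 3, 4, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' @rdname quad_area
#' @export
quad_centroid <- function(quad) colMeans(quad[, 1:2, drop = FALSE])

is_simple_quad <- function(quad) {
  # a quad is simple iff its two diagonals intersect (convex) or, when they
  # do not, no pair of opposite edges crosses
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  a <- quad[1, ]; b <- quad[2, ]; c <- quad[3, ]; d <- quad[4, ]
  !(seg_int(a, b, c, d) || seg_int(b, c, d, a))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Is a quadrilateral convex?
#' @param quad 4x2 corner matrix.
#' @export
is_convex_quad <- function(quad) {
  j <- c(2, 3, 4, 1); k <- c(3, 4, 1, 2)
  cr <- (quad[j, 1] - quad[, 1]) * (quad[k, 2] - quad[j, 2]) -
        (quad[j, 2] - quad[, 2]) * (quad[k, 1] - quad[j, 1])
  all(cr > 0) || all(cr < 0)
}

#' Bilinear shape functions of the 4-node isoparametric element
#'
#' N1 = (1-xi)(1-eta)/4, N2 = (1+xi)(1-eta)/4, N3 = (1+xi)(1+eta)/4,
#' N4 = (1-xi)(1+eta)/4.  They sum to 1 everywhere (partition of unity),
#' which makes the induced map affine-equivariant.
#'
#' @param xi,eta natural coordinates (vectors allowed).
#' @return n x 4 matrix of shape-function values.
#' @export
shape_functions <- function(xi, eta) {
  cbind((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
        (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}

#' Map natural coordinates to Cartesian coordinates of a section
#'
#' The transfinite (bilinear isoparametric) map sends the reference square
#' [-1,1]^2 onto the section quadrilateral: corner i of the square maps to
#' corner i of the section, and (0,0) to the corner mean.
#'
#' @param quad `section_quad` (or 4x2 matrix).
#' @param p natural coordinates: length-2 vector `c(xi, eta)` or n x 2 matrix.
#' @return Cartesian point(s), same shape as `p`.
#' @export
forward_map <- function(quad, p) {
  quad <- as_quad(quad)
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  out <- shape_functions(pm[, 1], pm[, 2]) %*% quad
  colnames(out) <- c("x", "y")
  if (is.matrix(p)) out else drop(out)
}

as_quad <- function(quad) {
  if (inherits(quad, "section_quad")) return(quad)
  section_quad(quad, check = TRUE)
}

#' Map a Cartesian point into the natural coordinates of a section
#'
#' Inverts the bilinear map by damped Newton iteration from the element
#' centre (0,0); the inversion is quadratic so Newton converges fast for
#' convex sections.  If Newton stalls, the solver reseeds from the best
#' point of a coarse 41x41 grid on [-1,1]^2 and restarts.  For non-convex
#' (but simple) quads the inversion may be multivalued; the solution
#' closest to (0,0) is returned and flagged.
#'
#' @param quad `section_quad`.
#' @param p Cartesian point `c(x, y)` or n x 2 matrix.
#' @param tol residual tolerance in the Cartesian frame units.
#' @param max_iter Newton iteration cap.
#' @return natural coordinates with attributes `outside` (logical: outside
#'   [-1,1]^2 beyond a small tolerance) and `multivalued` (non-convex quad).
#' @export
inverse_map <- function(quad, p, tol = 1e-9, max_iter = 50L) {
  quad <- as_quad(quad)
  pm <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  multi <- !is_convex_quad(quad)
  if (multi) warning("non-convex quadrilateral: inversion may be multivalued")
  res <- t(apply(pm, 1, function(pt) inverse_map_one(quad, pt, tol, max_iter)))
  out <- res[, 1:2, drop = FALSE]
  colnames(out) <- c("xi", "eta")
  outside <- apply(abs(out) > 1 + 1e-7, 1, any)
  if (!is.matrix(p)) { out <- drop(out); outside <- any(abs(out) > 1 + 1e-7) }
  structure(out, outside = outside, multivalued = multi)
}

inverse_map_one <- function(quad, pt, tol, max_iter) {
  newton <- function(q0) {
    q <- q0
    for (i in seq_len(max_iter)) {
      N <- shape_functions(q[1], q[2])
      r <- drop(N %*% quad) - pt
      if (sqrt(sum(r^2)) < tol) return(list(q = q, res = sqrt(sum(r^2))))
      dNdxi  <- c(-(1 - q[2]),  (1 - q[2]), (1 + q[2]), -(1 + q[2])) / 4
      dNdeta <- c(-(1 - q[1]), -(1 + q[1]), (1 + q[1]),  (1 - q[1])) / 4
      J <- rbind(drop(dNdxi %*% quad), drop(dNdeta %*% quad))  # rows d/dxi, d/deta
      det_j <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (abs(det_j) < 1e-14) return(list(q = q, res = sqrt(sum(r^2))))
      # solve t(J) %*% dq = r  (J rows are gradients of x,y wrt (xi,eta))
      dq <- solve(t(J), r)
      step <- 1
      repeat {
        qn <- q - step * dq
        Nn <- shape_functions(qn[1], qn[2])
        rn <- drop(Nn %*% quad) - pt
        if (sum(rn^2) < sum(r^2) || step < 1 / 64) break
        step <- step / 2
      }
      q <- q - step * dq
    }
    N <- shape_functions(q[1], q[2])
    list(q = q, res = sqrt(sum((drop(N %*% quad) - pt)^2)))
  }
  sol <- newton(c(0, 0))
  if (sol$res >= tol) {
    g <- seq(-1, 1, length.out = 41)
    gr <- as.matrix(expand.grid(xi = g, eta = g))
    fm <- shape_functions(gr[, 1], gr[, 2]) %*% quad
    d2 <- (fm[, 1] - pt[1])^2 + (fm[, 2] - pt[2])^2
    # prefer seeds close to the centre among near-minimal residuals
    ord <- order(d2, gr[, 1]^2 + gr[, 2]^2)
    for (idx in ord[1:5]) {
      sol2 <- newton(gr[idx, ])
      if (sol2$res < tol) { sol <- sol2; break }
      if (sol2$res < sol$res) sol <- sol2
    }
  }
  if (sol$res >= tol * 10 && sol$res > 1e-6)
    stop(sprintf("inverse_map failed to converge (best residual %.3g)", sol$res))
  c(sol$q, sol$res)
}

#' Propagate an ROI position from one section to another
#'
#' The point is expressed in the natural coordinates of its own section and
#' re-materialised at the same natural address in the target section; ROI
#' addresses are therefore independent of the gradual shape change along
#' a ribbon.
#'
#' @param quad_i source section.
#' @param quad_j target section.
#' @param p_i Cartesian point(s) in the source frame.
#' @return Cartesian point(s) in the target frame.
#' @export
propagate_roi <- function(quad_i, quad_j, p_i) {
  nat <- inverse_map(quad_i, p_i)
  if (any(attr(nat, "outside")))
    warning("ROI lies outside its source section")
  forward_map(quad_j, unclass_nat(nat))
}

unclass_nat <- function(x) { attributes(x)[c("outside", "multivalued")] <- NULL; x }

#' Assemble detected sections into a ribbon
#' @param sections list of `section_quad` in cutting order.
#' @export
ribbon <- function(sections) {
  stopifnot(length(sections) >= 1)
  if (length(sections) > 1) {
    cen <- t(vapply(sections, quad_centroid, numeric(2)))
    sep <- sqrt(rowSums(diff(cen)^2))
    if (any(sep < 1e-9)) stop("invalid-geometry: consecutive sections share a centroid")
  }
  structure(list(sections = sections), class = "at_ribbon")
}

#' @export
length.at_ribbon <- function(x) length(x$sections)

#' Cyclically align one quadrilateral's corners with a reference
#'
#' Both quads must have the same orientation; the rotation of the corner
#' cycle minimising the total corner distance to `ref` is returned.  Used
#' when comparing quads whose starting corner was chosen independently.
#'
#' @param quad,ref 4x2 corner matrices with equal orientation.
#' @export
align_corners <- function(quad, ref) {
  quad <- as.matrix(quad)[, 1:2]; ref <- as.matrix(ref)[, 1:2]
  if (sign(quad_area(quad)) != sign(quad_area(ref)))
    stop("corner-ordering convention mismatch (reversed orientation)")
  best <- NULL; best_d <- Inf
  for (s in 0:3) {
    idx <- ((s + 0:3) %% 4) + 1
    d <- sum((quad[idx, ] - ref)^2)
    if (d < best_d) { best_d <- d; best <- quad[idx, , drop = FALSE] }
  }
  section_quad(best, check = FALSE)
}

#' Canonicalise corner order of a quadrilateral
#'
#' Reorders corners so the cycle has positive shoelace area and starts at
#' the ribbon's leading (first-cut) edge: the cycle is rotated so the edge
#' from corner 1 to corner 2 is the one whose midpoint is highest in the
#' image (smallest y).  Ribbons are deposited roughly parallel to the
#' image y axis, so that edge faces the start of the ribbon.  Detection
#' uses this to enforce one ordering convention across a ribbon.
#'
#' @param quad 4x2 corner matrix in any cyclic order.
#' @export
order_corners <- function(quad) {
  quad <- as.matrix(quad)[, 1:2, drop = FALSE]
  if (quad_area(quad) < 0) quad <- quad[4:1, , drop = FALSE]
  nn <- c(2, 3, 4, 1)
  mid_y <- (quad[, 2] + quad[nn, 2]) / 2
  lead <- which.min(mid_y)
  idx <- ((lead - 1 + 0:3) %% 4) + 1
  section_quad(quad[idx, , drop = FALSE])
}
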