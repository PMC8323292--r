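#' Default synthetic-scene parameters
#'
#' The defaults emulate the study sample: six ribbons of trapezoidal
#' 150 nm sections (15 to 27 per ribbon, 126 in total) deposited on an ITO
#' coverslip, with gradual per-section shape change along each ribbon,
#' glue strips on the leading and trailing edges, one persistent dark
#' Golgi-like structure per ROI whose centroid drifts at most 0.5 um per
#' section, and a smooth focus surface.  Section face dimensions (60 x 45
#' um) are the package's own choice of a desk-scale section; the layout
#' fits comfortably inside a 22 x 22 mm coverslip.
#'
#' @return named list of generator parameters (micrometre units unless
#'   noted): layout counts, section geometry, per-section drift rates,
#'   ROI and focus-surface settings.
#' @export
scene_params <- function() {
  list(
    n_ribbons = 6L,
    sections_total = 126L,
    sections_range = c(15L, 27L),
    section_w = 60,            # leading-edge width, um
    section_h = 45,            # cutting pitch, um
    trapezoid_taper = 0.12,    # trailing edge shorter by this fraction
    section_gap = 3,           # visible seam between glued sections, um
    shrink_per_section = 0.002,
    shear_per_section = 0.0015,
    curvature_deg_per_section = 0,
    ribbon_tilt_deg = 2,       # max random tilt per ribbon
    ribbon_spacing = 45,       # gap between ribbon columns, um
    margin = 60,               # scene border, um
    n_rois = 1L,
    roi_drift = 0.5,           # max centroid drift per section, um
    glue_width = 4,            # glue strip width, um
    focus_range = 8            # peak-to-peak focus surface variation, um
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ribbon scene with full ground truth
#'
#' Produces the geometry every other module is tested against: section
#' quadrilaterals in stage micrometres (cutting order within each ribbon),
#' per-ROI ground-truth trajectories (one stage position per section of
#' the ROI's ribbon), a smooth focus surface, and the texture seed used by
#' the renderer.  Fully determined by `(params, seed)`.
#'
#' @param params parameter list; missing entries filled from
#'   [scene_params()].
#' @param seed integer RNG seed.
#' @return a `synthetic_scene`.
#' @export
generate_scene <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(scene_params(), params)
  with_seed(seed, {
    counts <- draw_section_counts(p$n_ribbons, p$sections_total, p$sections_range)
    ribbons <- vector("list", p$n_ribbons)
    x0 <- p$margin
    for (r in seq_len(p$n_ribbons)) {
      tilt <- stats::runif(1, -p$ribbon_tilt_deg, p$ribbon_tilt_deg) * pi / 180
      start <- c(x0 + p$section_w / 2, p$margin + p$section_h / 2 +
                   stats::runif(1, 0, 10))
      quads <- vector("list", counts[r])
      centre <- start
      theta <- tilt
      for (k in seq_len(counts[r])) {
        scale <- (1 - p$shrink_per_section)^(k - 1)
        wt <- p$section_w * scale
        wb <- wt * (1 - p$trapezoid_taper)
        h <- p$section_h * scale
        sh <- p$shear_per_section * (k - 1)
        local <- rbind(c(-wt / 2, -h / 2), c(wt / 2, -h / 2),
                       c(wb / 2, h / 2), c(-wb / 2, h / 2))
        local[, 1] <- local[, 1] + sh * local[, 2]
        rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
        quads[[k]] <- section_quad(sweep(local %*% t(rot), 2, centre, "+"))
        theta_next <- theta + p$curvature_deg_per_section * pi / 180
        step_len <- p$section_h * (scale + scale * (1 - p$shrink_per_section)) / 2 +
          p$section_gap
        # ribbon axis points down the image (+y); tilt/curvature bend it in x
        mid <- (theta + theta_next) / 2
        centre <- centre + step_len * c(-sin(mid), cos(mid))
        theta <- theta_next
      }
      ribbons[[r]] <- ribbon(quads)
      x0 <- x0 + p$section_w + p$ribbon_spacing
    }
    check_layout(ribbons)
    bounds <- scene_bounds(ribbons, p$margin)
    focus <- list(
      x0 = mean(bounds$xlim), y0 = mean(bounds$ylim),
      a = stats::runif(1, -1, 1), b = stats::runif(1, -1, 1),
      lx = diff(bounds$xlim) * stats::runif(1, 0.8, 1.4),
      ly = diff(bounds$ylim) * stats::runif(1, 0.8, 1.4),
      ph1 = stats::runif(1, 0, 2 * pi), ph2 = stats::runif(1, 0, 2 * pi),
      range = p$focus_range)
    rois <- lapply(seq_len(p$n_rois), function(i) {
      rb <- ((i - 1) %% p$n_ribbons) + 1
      nat <- stats::runif(2, -0.5, 0.5)
      quads <- ribbons[[rb]]$sections
      base <- t(vapply(quads, function(q) forward_map(q, nat), numeric(2)))
      ang <- stats::runif(length(quads), 0, 2 * pi)
      rad <- p$roi_drift * sqrt(stats::runif(length(quads)))
      drift <- apply(cbind(rad * cos(ang), rad * sin(ang)), 2, cumsum)
      drift <- sweep(drift, 2, drift[1, ])   # anchor section sits on the base point
      nb <- 4L
      blob_ang <- stats::runif(nb, 0, 2 * pi)
      blob_rad <- c(0, 2.5 * sqrt(stats::runif(nb - 1)))
      blobs <- data.frame(ox = blob_rad * cos(blob_ang),
                          oy = blob_rad * sin(blob_ang),
                          sigma = stats::runif(nb, 1.2, 2.2),
                          amp = stats::runif(nb, 0.25, 0.4))
      # centre the structure so its intensity-weighted centroid sits exactly
      # on the trajectory point
      w <- blobs$amp * blobs$sigma^2
      blobs$ox <- blobs$ox - stats::weighted.mean(blobs$ox, w)
      blobs$oy <- blobs$oy - stats::weighted.mean(blobs$oy, w)
      list(id = paste0("roi", i), ribbon = rb, natural = nat,
           trajectory = base + drift, blobs = blobs)
    })
    structure(list(params = p, seed = seed, section_counts = counts,
                   ribbons = ribbons, rois = rois, focus = focus,
                   bounds = bounds, tex_seed = seed * 977 + 13),
              class = "synthetic_scene")
  })
}

draw_section_counts <- function(n, total, range) {
  if (total < n * range[1] || total > n * range[2])
    stop("layout error: section total incompatible with per-ribbon range")
  counts <- rep(floor(total / n), n)
  counts <- counts + c(rep(1, total - sum(counts)), rep(0, n - (total - sum(counts))))
  # randomly redistribute while respecting the range
  for (i in seq_len(4 * n)) {
    a <- sample(n, 1); b <- sample(n, 1)
    if (a != b && counts[a] + 1 <= range[2] && counts[b] - 1 >= range[1]) {
      counts[a] <- counts[a] + 1; counts[b] <- counts[b] - 1
    }
  }
  counts
}

check_layout <- function(ribbons) {
  bb <- lapply(ribbons, function(rb) {
    cs <- do.call(rbind, lapply(rb$sections, unclass))
    c(min(cs[, 1]), max(cs[, 1]), min(cs[, 2]), max(cs[, 2]))
  })
  n <- length(bb)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bb[[i]][1] < bb[[j]][2] && bb[[j]][1] < bb[[i]][2] &&
        bb[[i]][3] < bb[[j]][4] && bb[[j]][3] < bb[[i]][4])
      stop("layout error: ribbons overlap")
  }
  invisible(TRUE)
}

scene_bounds <- function(ribbons, margin) {
  cs <- do.call(rbind, lapply(ribbons, function(rb)
    do.call(rbind, lapply(rb$sections, unclass))))
  list(xlim = c(min(cs[, 1]) - margin, max(cs[, 1]) + margin),
       ylim = c(min(cs[, 2]) - margin, max(cs[, 2]) + margin))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d ribbons, %d sections, %d ROI(s), seed %d\n",
              length(x$ribbons), sum(x$section_counts), length(x$rois), x$seed))
  invisible(x)
}

#' Ground-truth focus surface of a scene
#' @param scene a `synthetic_scene`.
#' @param x,y stage positions (um).
#' @return focus z in um.
#' @export
scene_focus_at <- function(scene, x, y) {
  f <- scene$focus
  lin <- f$a * (x - f$x0) + f$b * (y - f$y0)
  lin <- lin / max(abs(f$a) * diff(scene$bounds$xlim) / 2 +
                   abs(f$b) * diff(scene$bounds$ylim) / 2, 1e-9)
  wav <- sin(2 * pi * (x - f$x0) / f$lx + f$ph1) *
         sin(2 * pi * (y - f$y0) / f$ly + f$ph2)
  (f$range / 2) * (0.7 * lin + 0.3 * wav)
}

# --- deterministic value-noise texture (a pure function of stage um) ------
vnoise_hash <- function(ix, iy, seed) {
  h <- sin(ix * 127.1 + iy * 311.7 + seed * 0.5453) * 43758.5453
  h - floor(h)
}

vnoise <- function(x, y, scale, seed) {
  gx <- x / scale; gy <- y / scale
  ix <- floor(gx); iy <- floor(gy)
  fx <- gx - ix; fy <- gy - iy
  ux <- fx * fx * (3 - 2 * fx); uy <- fy * fy * (3 - 2 * fy)
  v00 <- vnoise_hash(ix, iy, seed);     v10 <- vnoise_hash(ix + 1, iy, seed)
  v01 <- vnoise_hash(ix, iy + 1, seed); v11 <- vnoise_hash(ix + 1, iy + 1, seed)
  (v00 * (1 - ux) + v10 * ux) * (1 - uy) + (v01 * (1 - ux) + v11 * ux) * uy
}

texture_field <- function(x, y, seed) {
  # octave lattices are rotated against each other so the value-noise grid
  # leaves no common periodicity in the rendered texture
  u2 <- 0.921 * x - 0.391 * y; v2 <- 0.391 * x + 0.921 * y
  u3 <- 0.659 * x - 0.753 * y; v3 <- 0.753 * x + 0.659 * y
  0.6 * (vnoise(x, y, 6, seed) - 0.5) +
  0.3 * (vnoise(u2, v2, 1.7, seed + 7) - 0.5) +
  0.25 * (vnoise(u3, v3, 0.4, seed + 19) - 0.5)
}

# tissue texture of one section: sampled in section-local coordinates
# (anchored to the section centroid) and blended between two depth layers,
# so consecutive sections cut through slowly changing 3D structure the way
# real serial sections do - neighbouring sections correlate strongly,
# distant ones decorrelate
section_texture <- function(px, py, quad, depth, seed, dz = 0.12) {
  cen <- quad_centroid(quad)
  u <- px - cen[1]; v <- py - cen[2]
  z <- depth * dz
  zi <- floor(z); f <- z - zi
  (1 - f) * texture_field(u, v, seed + 101 * zi) +
    f * texture_field(u, v, seed + 101 * (zi + 1))
}

# squared distance from points to a segment, vectorised over points
seg_dist <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx * vx + vy * vy
  t <- ((px - a[1]) * vx + (py - a[2]) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

#' Render a rectangular window of the scene
#'
#' Brightfield-like rendering: bright background, darker textured section
#' interiors, dark boundary outlines, darker glue strips on the leading and
#' trailing edges, and high-contrast dark ROI structures.  All texture is a
#' deterministic function of stage coordinates, so windows rendered at
#' different centres or pixel sizes agree where they overlap.
#'
#' @param scene a `synthetic_scene`.
#' @param origin_um stage position (um) of the window's top-left corner.
#' @param nx,ny window size in pixels (cols, rows).
#' @param px_per_um pixels per micrometre.
#' @param defocus_sigma_px optional Gaussian defocus blur (px).
#' @return numeric matrix in `[0,1]` (rows = y, cols = x), unquantised.
#' @export
render_region <- function(scene, origin_um, nx, ny, px_per_um,
                          defocus_sigma_px = 0) {
  xs <- origin_um[1] + (seq_len(nx) - 0.5) / px_per_um
  ys <- origin_um[2] + (seq_len(ny) - 0.5) / px_per_um
  ts <- scene$tex_seed
  canvas <- 0.88 + 0.04 * (vnoise(matrix(xs, ny, nx, byrow = TRUE),
                                  matrix(ys, ny, nx), 15, ts + 31) - 0.5)
  gw <- scene$params$glue_width
  bw <- 0.5  # boundary line half-width, um
  pad <- gw + 1.5
  depth_base <- cumsum(c(0L, vapply(scene$ribbons, function(r)
    length(r$sections), integer(1))))
  for (ri in seq_along(scene$ribbons)) for (ki in seq_along(scene$ribbons[[ri]]$sections)) {
    q <- scene$ribbons[[ri]]$sections[[ki]]
    depth <- depth_base[ri] + ki   # cutting depth through the block
    cx <- range(q[, 1]); cy <- range(q[, 2])
    jr <- which(xs >= cx[1] - pad & xs <= cx[2] + pad)
    ir <- which(ys >= cy[1] - pad & ys <= cy[2] + pad)
    if (!length(jr) || !length(ir)) next
    px <- matrix(xs[jr], length(ir), length(jr), byrow = TRUE)
    py <- matrix(ys[ir], length(ir), length(jr))
    nn <- c(2, 3, 4, 1)
    cr1 <- (q[2, 1] - q[1, 1]) * (py - q[1, 2]) - (q[2, 2] - q[1, 2]) * (px - q[1, 1])
    cr2 <- (q[3, 1] - q[2, 1]) * (py - q[2, 2]) - (q[3, 2] - q[2, 2]) * (px - q[2, 1])
    cr3 <- (q[4, 1] - q[3, 1]) * (py - q[3, 2]) - (q[4, 2] - q[3, 2]) * (px - q[3, 1])
    cr4 <- (q[1, 1] - q[4, 1]) * (py - q[4, 2]) - (q[1, 2] - q[4, 2]) * (px - q[4, 1])
    inside <- cr1 > 0 & cr2 > 0 & cr3 > 0 & cr4 > 0
    d <- pmin(seg_dist(px, py, q[1, ], q[2, ]), seg_dist(px, py, q[2, ], q[3, ]),
              seg_dist(px, py, q[3, ], q[4, ]), seg_dist(px, py, q[4, ], q[1, ]))
    val <- canvas[ir, jr, drop = FALSE]
    tex <- section_texture(px, py, q, depth, ts)
    interior <- 0.60 + 0.20 * tex
    val[inside] <- interior[inside]
    dglue <- pmin(seg_dist(px, py, q[1, ], q[2, ]), seg_dist(px, py, q[3, ], q[4, ]))
    glue <- inside & dglue < gw
    val[glue] <- val[glue] * 0.72
    border <- d < bw
    val[border] <- pmin(val[border], 0.16 + 0.10 * tex[border])
    canvas[ir, jr] <- val
  }
  for (roi in scene$rois) {
    traj <- roi$trajectory
    near <- which(traj[, 1] > origin_um[1] - 15 & traj[, 1] < max(xs) + 15 &
                  traj[, 2] > origin_um[2] - 15 & traj[, 2] < max(ys) + 15)
    for (k in near) {
      for (bidx in seq_len(nrow(roi$blobs))) {
        b <- roi$blobs[bidx, ]
        bx <- traj[k, 1] + b$ox; by <- traj[k, 2] + b$oy
        jr <- which(abs(xs - bx) < 4 * b$sigma)
        ir <- which(abs(ys - by) < 4 * b$sigma)
        if (!length(jr) || !length(ir)) next
        gx <- exp(-((xs[jr] - bx)^2) / (2 * b$sigma^2))
        gy <- exp(-((ys[ir] - by)^2) / (2 * b$sigma^2))
        canvas[ir, jr] <- canvas[ir, jr] - b$amp * outer(gy, gx)
      }
    }
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  if (defocus_sigma_px > 0.3)
    canvas <- pmin(pmax(as_mat(EBImage::gblur(canvas, sigma = defocus_sigma_px)), 0), 1)
  canvas
}

#' Render the full overview image of a scene
#'
#' @param scene a `synthetic_scene`.
#' @param px_per_um pixels per micrometre (2.96 matches a 20x overview).
#' @param tiles optional list(rows, cols, overlap, jitter_px, seed): also
#'   return the overview cut into an overlapping tile grid with seeded
#'   position jitter, for stitching tests.
#' @param max_pixels guard against accidental huge rasters.
#' @return an `overview_image` (8-bit quantised).  Attributes: `origin_um`
#'   (stage position of the top-left corner), `truth_px` (list of ribbons,
#'   each a list of ground-truth quads in overview pixel coordinates),
#'   `roi_px` (per-ROI trajectory in pixel coordinates), and optionally
#'   `tile_grid` + `tile_truth` (true tile positions).
#' @export
render_overview <- function(scene, px_per_um = 2.96, tiles = NULL,
                            max_pixels = 6e7) {
  b <- scene$bounds
  origin <- c(b$xlim[1], b$ylim[1])
  nx <- ceiling(diff(b$xlim) * px_per_um)
  ny <- ceiling(diff(b$ylim) * px_per_um)
  if (as.numeric(nx) * ny > max_pixels)
    stop(sprintf("size error: %d x %d raster exceeds max_pixels", ny, nx))
  img <- render_region(scene, origin, nx, ny, px_per_um)
  img <- round(img * 255) / 255
  to_px <- function(pts) sweep(pts, 2, origin) * px_per_um + 0.5
  truth <- lapply(scene$ribbons, function(rb)
    lapply(rb$sections, function(q) section_quad(to_px(unclass(q)))))
  roi_px <- lapply(scene$rois, function(r) to_px(r$trajectory))
  out <- overview_image(img, 1 / px_per_um, 8L)
  attr(out, "origin_um") <- origin
  attr(out, "truth_px") <- truth
  attr(out, "roi_px") <- roi_px
  if (!is.null(tiles)) {
    tg <- cut_tiles(img, tiles)
    attr(out, "tile_grid") <- tg$grid
    attr(out, "tile_truth") <- tg$truth
  }
  out
}

cut_tiles <- function(img, tiles) {
  t0 <- utils::modifyList(list(rows = 2L, cols = 2L, overlap = 0.2,
                               jitter_px = 0, seed = 1L), tiles)
  H <- nrow(img); W <- ncol(img)
  th <- floor(H / (1 + (t0$rows - 1) * (1 - t0$overlap)))
  tw <- floor(W / (1 + (t0$cols - 1) * (1 - t0$overlap)))
  with_seed(t0$seed, {
    tl <- list(); truth <- NULL
    for (r in seq_len(t0$rows)) for (c in seq_len(t0$cols)) {
      y0 <- round((r - 1) * th * (1 - t0$overlap))
      x0 <- round((c - 1) * tw * (1 - t0$overlap))
      if (t0$jitter_px > 0 && (r > 1 || c > 1)) {
        y0 <- y0 + sample(-t0$jitter_px:t0$jitter_px, 1)
        x0 <- x0 + sample(-t0$jitter_px:t0$jitter_px, 1)
      }
      y0 <- min(max(y0, 0), H - th); x0 <- min(max(x0, 0), W - tw)
      tl[[length(tl) + 1]] <- img[y0 + seq_len(th), x0 + seq_len(tw)]
      truth <- rbind(truth, c(x = x0, y = y0))
    }
    list(grid = tile_grid(tl, t0$rows, t0$cols, t0$overlap),
         truth = as.data.frame(truth))
  })
}

#' Apply a seeded degradation to an 8-bit image
#'
#' Emulates the robustness protocol used to stress section detection:
#' additive Gaussian noise (sigma in 8-bit gray levels), salt-and-pepper
#' noise, erasure of section corners or sides (replaced by background
#' intensity), and dark glue blobs.
#'
#' @param img an `overview_image` or matrix in `[0,1]`.
#' @param model list(name, ...): one of
#'   `gaussian(sigma)`, `salt_pepper(fraction)`, `erase_corners(k, radius_px)`,
#'   `erase_sides(k, width_px)`, `glue_blobs(n)`.
#' @param truth_px ground-truth section quads in pixel coordinates (list of
#'   ribbons of quads); required by the erasure models.
#' @param seed RNG seed.
#' @return same type as `img`, clipped to `[0,1]` and re-quantised to 8 bit.
#' @export
degrade_image <- function(img, model, truth_px = NULL, seed = 1L) {
  is_ov <- inherits(img, "overview_image")
  x <- if (is_ov) img$pixels else img
  stopifnot(is.matrix(x))
  name <- model$name
  bg <- as.numeric(stats::quantile(x, 0.9))
  x <- with_seed(seed, switch(
    name,
    gaussian = x + stats::rnorm(length(x), 0, model$sigma / 255),
    salt_pepper = {
      n <- round(model$fraction * length(x))
      idx <- sample(length(x), n)
      x[idx] <- sample(c(0, 1), n, replace = TRUE)
      x
    },
    erase_corners = {
      r <- if (is.null(model$radius_px)) 15 else model$radius_px
      for (rb in truth_px) for (q in rb) {
        ks <- sample(4, model$k)
        for (ci in ks) x <- paint_disc(x, q[ci, 1], q[ci, 2], r, bg)
      }
      x
    },
    erase_sides = {
      w <- if (is.null(model$width_px)) 6 else model$width_px
      nn <- c(2, 3, 4, 1)
      for (rb in truth_px) for (q in rb) {
        ks <- sample(4, model$k)
        for (si in ks) x <- paint_band(x, q[si, ], q[nn[si], ], w, bg)
      }
      x
    },
    glue_blobs = {
      for (i in seq_len(model$n)) {
        cx <- stats::runif(1, 1, ncol(x)); cy <- stats::runif(1, 1, nrow(x))
        x <- paint_disc(x, cx, cy, stats::runif(1, 8, 25), 0.08)
      }
      x
    },
    stop(sprintf("config error: unknown degradation model '%s'", name))))
  x <- round(pmin(pmax(x, 0), 1) * 255) / 255
  if (is_ov) { img$pixels <- x; img } else x
}

paint_disc <- function(x, cx, cy, r, value) {
  jr <- max(1, floor(cx - r)):min(ncol(x), ceiling(cx + r))
  ir <- max(1, floor(cy - r)):min(nrow(x), ceiling(cy + r))
  if (!length(jr) || !length(ir)) return(x)
  m <- outer((ir - cy)^2, (jr - cx)^2, "+") <= r^2
  sub <- x[ir, jr, drop = FALSE]; sub[m] <- value
  x[ir, jr] <- sub
  x
}

paint_band <- function(x, a, b, w, value) {
  jr <- max(1, floor(min(a[1], b[1]) - w)):min(ncol(x), ceiling(max(a[1], b[1]) + w))
  ir <- max(1, floor(min(a[2], b[2]) - w)):min(nrow(x), ceiling(max(a[2], b[2]) + w))
  if (!length(jr) || !length(ir)) return(x)
  px <- matrix(jr, length(ir), length(jr), byrow = TRUE)
  py <- matrix(ir, length(ir), length(jr))
  m <- seg_dist(px, py, a, b) <= w
  sub <- x[ir, jr, drop = FALSE]; sub[m] <- value
  x[ir, jr] <- sub
  x
}

#' Serialize / restore a synthetic scene
#'
#' A scene is fully determined by its `(params, seed)` pair, so the JSON
#' stores exactly that and [read_scene()] regenerates the scene bit for
#' bit.
#'
#' @param scene a `synthetic_scene`.
#' @param path JSON file path.
#' @export
write_scene <- function(scene, path) {
  jsonlite::write_json(list(params = scene$params, seed = scene$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$params
  p$sections_range <- as.integer(p$sections_range)
  generate_scene(p, as.integer(obj$seed))
}

#' Export scene ground truth as CSV tables
#'
#' Writes `sections.csv` (ribbon, section, corner, x_um, y_um) and
#' `rois.csv` (roi_id, section, x_um, y_um) so detection and navigation
#' results can be scored without touching the scene internals.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory.
#' @export
export_ground_truth <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  secs <- NULL
  for (r in seq_along(scene$ribbons))
    for (k in seq_along(scene$ribbons[[r]]$sections)) {
      q <- unclass(scene$ribbons[[r]]$sections[[k]])
      secs <- rbind(secs, data.frame(ribbon = r, section = k, corner = 1:4,
                                     x_um = q[, 1], y_um = q[, 2]))
    }
  utils::write.csv(secs, file.path(dir, "sections.csv"), row.names = FALSE)
  rois <- do.call(rbind, lapply(scene$rois, function(roi)
    data.frame(roi_id = roi$id, section = seq_len(nrow(roi$trajectory)),
               x_um = roi$trajectory[, 1], y_um = roi$trajectory[, 2])))
  utils::write.csv(rois, file.path(dir, "rois.csv"), row.names = FALSE)
  invisible(dir)
}

#' Declared pixel sizes of the magnification ladder
#'
#' 20x and 100x are the light-microscope steps; 4kx, 12kx and 30kx the
#' electron-microscope steps.
#'
#' @return named numeric vector, pixels per micrometre.
#' @export
mag_pixel_sizes <- function() {
  c("20x" = 2.96, "100x" = 15.38, "4kx" = 43.03,
    "12kx" = 129.08, "30kx" = 322.69)
}

#' Simulated microscope over a synthetic scene
#'
#' Implements the microscope contract used by [acquire_stack()]:
#' `move_to(c(x, y))` (stage um), `set_focus(z)`, `acquire(mag)`.  Stage
#' positions are interpreted in the calibrated stage frame whose origin
#' sits at `stage_origin_um` in scene coordinates (the corner the user
#' zeroed the stage on).  Optional seeded Gaussian repeatability jitter is
#' applied to every move; defocus relative to the scene's ground-truth
#' focus surface is rendered as Gaussian blur.
#'
#' @param scene a `synthetic_scene`.
#' @param stage_origin_um scene position (um) of the stage origin.
#' @param fov_px field of view in pixels (used for every magnification).
#' @param jitter_um standard deviation of stage repeatability jitter (um).
#' @param seed seed for the jitter stream.
#' @param mags named px/um table, by default [mag_pixel_sizes()].
#' @return a `sim_microscope`: list of closures plus a `log` environment
#'   recording commanded and actual positions of every acquisition.
#' @export
simulated_microscope <- function(scene, stage_origin_um = c(0, 0),
                                 fov_px = 200L, jitter_um = 0, seed = 1L,
                                 mags = mag_pixel_sizes()) {
  st <- new.env(parent = emptyenv())
  st$pos <- c(0, 0); st$z <- 0; st$n <- 0L
  st$log <- list()
  rng <- with_seed(seed, stats::runif(1))  # warm-up; per-move draws below
  scope <- list(
    move_to = function(pos_um) { st$pos <- as.numeric(pos_um); invisible(NULL) },
    set_focus = function(z_um) { st$z <- as.numeric(z_um); invisible(NULL) },
    acquire = function(mag) {
      ppu <- mags[[mag]]
      if (is.null(ppu)) stop(sprintf("unknown magnification '%s'", mag))
      st$n <- st$n + 1L
      jit <- c(0, 0)
      if (jitter_um > 0)
        jit <- with_seed(seed + 7919L * st$n, stats::rnorm(2, 0, jitter_um))
      actual <- stage_origin_um + st$pos + jit
      b <- scene$bounds
      if (actual[1] < b$xlim[1] - 50 || actual[1] > b$xlim[2] + 50 ||
          actual[2] < b$ylim[1] - 50 || actual[2] > b$ylim[2] + 50)
        stop("bounds error: stage position outside scene")
      true_z <- scene_focus_at(scene, actual[1], actual[2])
      dz <- abs(st$z - true_z)
      sig <- 0.5 * dz * (ppu / mags[["20x"]])
      half <- (fov_px / 2) / ppu
      img <- render_region(scene, actual - half, fov_px, fov_px, ppu,
                           defocus_sigma_px = sig)
      img <- round(img * 255) / 255
      st$log[[st$n]] <- list(commanded = st$pos, actual_scene = actual,
                             jitter = jit, mag = mag, defocus = dz)
      attr(img, "pixel_size") <- 1 / ppu
      img
    },
    pixel_size = function(mag) 1 / mags[[mag]],
    state = st)
  class(scope) <- "sim_microscope"
  scope
}
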