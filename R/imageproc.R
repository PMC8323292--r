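#' Overview image container
#'
#' Pixels are stored as a numeric matrix in `[0, 1]` (rows = y, cols = x);
#' `bit_depth` records the acquisition depth used when writing TIFFs.
#'
#' @param pixels numeric matrix, values in `[0, 1]`.
#' @param pixel_size micrometres per pixel.
#' @param bit_depth 8 or 16.
#' @export
overview_image <- function(pixels, pixel_size, bit_depth = 8L) {
  stopifnot(is.matrix(pixels), pixel_size > 0, bit_depth %in% c(8L, 16L))
  if (any(dim(pixels) < 64))
    stop("overview image must be at least 64x64 pixels")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "overview_image")
}

#' @export
print.overview_image <- function(x, ...) {
  cat(sprintf("overview_image: %d x %d px, %.4f um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$bit_depth))
  invisible(x)
}

#' Read / write an overview image as grayscale TIFF
#'
#' The pixel size (micrometres per pixel) travels in a JSON sidecar file
#' `<path>.meta.json` next to the TIFF; when reading, it is recovered from
#' the sidecar unless overridden.
#'
#' @param path TIFF file path.
#' @param pixel_size um/px override when no sidecar is present.
#' @export
read_overview <- function(path, pixel_size = NULL) {
  px <- tiff::readTIFF(path, info = TRUE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  info <- attributes(px)
  meta_path <- paste0(path, ".meta.json")
  if (is.null(pixel_size)) {
    if (file.exists(meta_path))
      pixel_size <- jsonlite::read_json(meta_path)$pixel_size_um
    else stop("no metadata sidecar for TIFF; supply pixel_size")
  }
  bits <- if (!is.null(info$bits.per.sample)) as.integer(info$bits.per.sample) else 8L
  overview_image(matrix(as.numeric(px), nrow(px), ncol(px)), pixel_size, bits)
}

#' @rdname read_overview
#' @param img an `overview_image`.
#' @export
write_overview <- function(img, path) {
  stopifnot(inherits(img, "overview_image"))
  tiff::writeTIFF(pmin(pmax(img$pixels, 0), 1), path,
                  bits.per.sample = img$bit_depth,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = img$pixel_size,
                            bit_depth = img$bit_depth),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Tile grid for overview stitching
#'
#' @param tiles row-major list of grayscale matrices (all the same shape).
#' @param rows,cols grid dimensions.
#' @param nominal_overlap nominal overlap fraction between adjacent tiles.
#' @export
tile_grid <- function(tiles, rows, cols, nominal_overlap = 0.2) {
  stopifnot(length(tiles) == rows * cols, rows >= 1, cols >= 1,
            nominal_overlap > 0, nominal_overlap < 0.5)
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all tiles must have the same shape")
  structure(list(tiles = tiles, rows = rows, cols = cols,
                 nominal_overlap = nominal_overlap),
            class = "tile_grid")
}

#' Stitch a grid of overview tiles into one mosaic
#'
#' Pairwise offsets between adjacent tiles are estimated by phase
#' correlation on their nominal overlap strips; a global least-squares
#' solve over the grid graph turns the pairwise estimates into absolute
#' tile positions (tile 1 anchored at the origin), and tiles are composited
#' with linear feather blending in the overlaps.  Featureless overlaps fall
#' back to the nominal offsets with a warning.
#'
#' @param grid a `tile_grid`.
#' @param pixel_size um/px of the tiles (propagated to the mosaic).
#' @param min_confidence peak-ratio threshold below which an estimated
#'   offset is replaced by the nominal one.
#' @return an `overview_image`; attribute `offsets` holds the estimated
#'   absolute tile positions (px) and attribute `pair_offsets` the pairwise
#'   estimates with confidences.
#' @export
grid_stitch <- function(grid, pixel_size = 1, min_confidence = 0.4) {
  stopifnot(inherits(grid, "tile_grid"))
  tiles <- grid$tiles
  nt <- length(tiles)
  h <- nrow(tiles[[1]]); w <- ncol(tiles[[1]])
  if (nt == 1)
    return(structure(overview_image(tiles[[1]], pixel_size),
                     offsets = data.frame(tile = 1L, x = 0, y = 0)))
  ov <- grid$nominal_overlap
  idx <- function(r, c) (r - 1L) * grid$cols + c
  pairs <- list()
  for (r in seq_len(grid$rows)) for (c in seq_len(grid$cols)) {
    if (c < grid$cols)
      pairs[[length(pairs) + 1]] <- list(i = idx(r, c), j = idx(r, c + 1), dir = "h")
    if (r < grid$rows)
      pairs[[length(pairs) + 1]] <- list(i = idx(r, c), j = idx(r + 1, c), dir = "v")
  }
  est <- lapply(pairs, function(p) {
    a <- tiles[[p$i]]; b <- tiles[[p$j]]
    if (p$dir == "h") {
      ow <- min(w, round(w * ov) + 16)
      sa <- a[, (w - ow + 1):w, drop = FALSE]
      sb <- b[, 1:ow, drop = FALSE]
      pc <- phase_correlate(sa, sb, upsample = 10, window = TRUE)
      nominal <- c(round(w * (1 - ov)), 0)
      off <- c((w - ow) - pc$shift[["dx"]], -pc$shift[["dy"]])
    } else {
      oh <- min(h, round(h * ov) + 16)
      sa <- a[(h - oh + 1):h, , drop = FALSE]
      sb <- b[1:oh, , drop = FALSE]
      pc <- phase_correlate(sa, sb, upsample = 10, window = TRUE)
      nominal <- c(0, round(h * (1 - ov)))
      off <- c(-pc$shift[["dx"]], (h - oh) - pc$shift[["dy"]])
    }
    plausible <- all(abs(off - nominal) < c(w, h) * ov * 1.5 + 10)
    if (pc$confidence < min_confidence || !plausible) {
      warning("featureless or implausible overlap; falling back to nominal offset")
      off <- nominal; conf <- 0
    } else conf <- pc$confidence
    c(i = p$i, j = p$j, dx = off[1], dy = off[2], conf = conf)
  })
  est <- as.data.frame(do.call(rbind, est))
  # global least squares: position_j - position_i = (dx, dy); tile 1 at 0
  A <- matrix(0, nrow(est) + 1, nt)
  A[cbind(seq_len(nrow(est)), est$i)] <- -1
  A[cbind(seq_len(nrow(est)), est$j)] <- 1
  A[nrow(est) + 1, 1] <- 1
  px <- qr.solve(A, c(est$dx, 0))
  py <- qr.solve(A, c(est$dy, 0))
  pos <- cbind(x = round(px - min(px)), y = round(py - min(py)))
  H <- max(pos[, "y"]) + h; W <- max(pos[, "x"]) + w
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  ramp <- max(1, round(0.5 * ov * min(h, w)))
  fw <- outer(feather_profile(h, ramp), feather_profile(w, ramp))
  for (t in seq_len(nt)) {
    ys <- pos[t, "y"] + seq_len(h); xs <- pos[t, "x"] + seq_len(w)
    acc[ys, xs] <- acc[ys, xs] + tiles[[t]] * fw
    wacc[ys, xs] <- wacc[ys, xs] + fw
  }
  mosaic <- acc / pmax(wacc, 1e-12)
  structure(overview_image(mosaic, pixel_size),
            offsets = data.frame(tile = seq_len(nt), x = pos[, "x"], y = pos[, "y"]),
            pair_offsets = est)
}

feather_profile <- function(n, ramp) {
  d <- pmin(seq_len(n) - 1, n - seq_len(n))
  pmin(d / ramp, 1) * (1 - 1e-6) + 1e-6
}

#' Preprocess an overview image into an edge-response map
#'
#' Runs the ordered, individually switchable pipeline that turns the
#' brightfield overview into a map whose maxima trace the section
#' boundaries: (1) percentile contrast normalisation, (2) Gaussian blur,
#' (3) Laplacian filter (magnitude), (4) Otsu threshold to a boundary
#' mask, (5) connected-component size filter, (6) morphological closing.
#' The returned map is the Laplacian magnitude gated by the cleaned mask
#' and lightly smoothed so the active contour sees wide basins of
#' attraction.
#'
#' @param img an `overview_image` (or plain matrix in `[0,1]`).
#' @param params list of parameters: `stages` (character vector choosing
#'   stages, default all), `p_low`/`p_high` (stretch percentiles,
#'   0.005/0.995), `laplacian_sign` ("positive", "negative" or "magnitude"),
#'   0.005/0.995), `sigma_blur` (px, 2), `min_area` (px^2, 100),
#'   `close_size` (brush diameter, 5), `sigma_basin` (final smoothing, 2).
#' @return an `edge_map`: numeric matrix (same shape, non-negative, max 1),
#'   with attribute `stages` recording the executed stages and parameters.
#' @export
preprocess_overview <- function(img, params = list()) {
  px <- if (inherits(img, "overview_image")) img$pixels else img
  stopifnot(is.matrix(px))
  p <- utils::modifyList(list(
    stages = c("normalize", "blur", "laplacian", "threshold",
               "size_filter", "smooth"),
    p_low = 0.005, p_high = 0.995, sigma_blur = 1.5,
    laplacian_sign = "positive",
    min_area = 100, close_size = 5, sigma_basin = 1.5), params)
  ran <- list()
  x <- px
  if ("normalize" %in% p$stages) {
    q <- stats::quantile(x, c(p$p_low, p$p_high), names = FALSE)
    if (q[2] - q[1] > 1e-12) x <- (x - q[1]) / (q[2] - q[1])
    x <- pmin(pmax(x, 0), 1)
    ran$normalize <- list(p_low = p$p_low, p_high = p$p_high)
  }
  if ("blur" %in% p$stages && p$sigma_blur > 0) {
    x <- as_mat(EBImage::gblur(x, sigma = p$sigma_blur))
    ran$blur <- list(sigma = p$sigma_blur)
  }
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  if ("laplacian" %in% p$stages) {
    lap <- as_mat(EBImage::filter2(x, lap_kernel))
    # sections and their outlines are darker than the substrate, so
    # boundaries are intensity minima: keep the positive lobe only, which
    # peaks at dark line centres and suppresses bright ridges (e.g. the
    # seam between adjacent sections)
    x <- switch(p$laplacian_sign,
                positive = pmax(lap, 0),
                negative = pmax(-lap, 0),
                magnitude = abs(lap))
    ran$laplacian <- list(kernel = "4-neighbour", sign = p$laplacian_sign)
  }
  resp <- x
  if (max(resp) > 0) resp <- resp / max(resp)
  mask <- NULL
  if ("threshold" %in% p$stages) {
    thr <- EBImage::otsu(EBImage::Image(resp), range = c(0, 1))
    mask <- resp > thr
    if (!any(mask)) stop("empty foreground after stage 'threshold'")
    ran$threshold <- list(method = "otsu", value = thr)
  }
  if (!is.null(mask) && "size_filter" %in% p$stages) {
    lab <- as_mat(EBImage::bwlabel(mask))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= p$min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    if (!any(mask)) stop("empty foreground after stage 'size_filter'")
    ran$size_filter <- list(min_area = p$min_area)
  }
  if (!is.null(mask) && "smooth" %in% p$stages) {
    brush <- EBImage::makeBrush(p$close_size, shape = "disc")
    mask <- as_mat(EBImage::closing(mask, brush)) > 0
    ran$smooth <- list(close_size = p$close_size)
  }
  out <- if (is.null(mask)) resp else resp * mask
  if (p$sigma_basin > 0) out <- as_mat(EBImage::gblur(out, sigma = p$sigma_basin))
  out[out < 0] <- 0
  if (max(out) > 0) out <- out / max(out)
  structure(out, class = c("edge_map", "matrix"), stages = ran)
}

as_mat <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}
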