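#' Subpixel translation estimation by phase correlation
#'
#' Estimates the displacement of image `b` relative to image `a` from the
#' normalised cross-power spectrum.  Because spectral whitening can
#' produce alias peaks on self-similar content, the strongest few
#' correlation peaks are validated against the real-space correlation of
#' the overlapping region and the best-supported peak is kept; it is then
#' refined to subpixel precision by evaluating an upsampled discrete
#' Fourier transform around the peak (matrix-multiply DFT).
#'
#' The returned shift `(dx, dy)` is the displacement of the *content* of
#' `b` with respect to `a` in pixels: `b[y, x] ~ a[y - dy, x - dx]`.
#'
#' @param a,b numeric matrices of identical dimensions (rows = y, cols = x).
#' @param upsample subpixel upsampling factor (10 gives 0.1 px resolution).
#' @param window apply a Hann window before transforming (reduces wrap-around
#'   edge artefacts; recommended for acquired frames).
#' @param n_candidates number of correlation peaks validated in real space.
#' @return list with `shift = c(dx, dy)` and `confidence`: the Pearson
#'   correlation of the overlap at the chosen shift (~1 for a clean match,
#'   ~0 for featureless or unrelated input).
#' @export
phase_correlate <- function(a, b, upsample = 10L, window = TRUE,
                            n_candidates = 5L) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  a0 <- a - mean(a); b0 <- b - mean(b)
  if (sqrt(mean(a0^2)) < 1e-12 || sqrt(mean(b0^2)) < 1e-12)
    return(list(shift = c(dx = 0, dy = 0), confidence = 0))
  aw <- a0; bw <- b0
  if (window) {
    W <- outer(hann(nr), hann(nc))
    aw <- a0 * W; bw <- b0 * W
  }
  Fa <- stats::fft(aw); Fb <- stats::fft(bw)
  cps <- Fb * Conj(Fa)
  cps <- cps / pmax(Mod(cps), 1e-12)
  r <- Mod(stats::fft(cps, inverse = TRUE)) / (nr * nc)
  # top integer peaks, 5x5 exclusion between them
  cand <- NULL
  rm <- r
  for (i in seq_len(n_candidates)) {
    pk <- arrayInd(which.max(rm), dim(rm))
    cand <- rbind(cand, c(dy = wrap_freq(pk[1] - 1, nr),
                          dx = wrap_freq(pk[2] - 1, nc), val = r[pk]))
    rows <- ((pk[1] - 3):(pk[1] + 3) - 1) %% nr + 1
    cols <- ((pk[2] - 3):(pk[2] + 3) - 1) %% nc + 1
    rm[rows, cols] <- -Inf
  }
  sc <- apply(cand, 1, function(cc) shift_cor(a0, b0, cc["dy"], cc["dx"]))
  best <- which.max(sc)
  dy <- cand[best, "dy"]; dx <- cand[best, "dx"]
  confidence <- max(sc[best], 0)
  if (upsample > 1) {
    half <- 1.5
    uy <- dy + seq(-half, half, by = 1 / upsample)
    ux <- dx + seq(-half, half, by = 1 / upsample)
    fy <- wrap_freq(0:(nr - 1), nr) / nr
    fx <- wrap_freq(0:(nc - 1), nc) / nc
    Ey <- exp(2i * pi * outer(uy, fy))          # |uy| x nr
    Ex <- exp(2i * pi * outer(fx, ux))          # nc x |ux|
    R <- Mod(Ey %*% cps %*% Ex)
    ij <- arrayInd(which.max(R), dim(R))
    dy <- uy[ij[1]]; dx <- ux[ij[2]]
  }
  list(shift = c(dx = dx, dy = dy), confidence = confidence)
}

# Pearson correlation of the non-wrapped overlap for the hypothesis that
# the content of b is displaced by (dx, dy): b[y, x] = a[y - dy, x - dx]
shift_cor <- function(a, b, dy, dx) {
  nr <- nrow(a); nc <- ncol(a)
  ya <- max(1, 1 - dy):min(nr, nr - dy)
  xa <- max(1, 1 - dx):min(nc, nc - dx)
  if (length(ya) < 8 || length(xa) < 8 ||
      length(ya) * length(xa) < 0.2 * nr * nc) return(-Inf)
  va <- as.vector(a[ya, xa])
  vb <- as.vector(b[ya + dy, xa + dx])
  if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12) return(0)
  stats::cor(va, vb)
}

hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

wrap_freq <- function(k, n) ifelse(k > n / 2, k - n, k)
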