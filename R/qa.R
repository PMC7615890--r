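#' Voxel-wise time-series quality maps
#'
#' Computes the first-order maps (mean, temporal SD, tSNR) together with
#' the higher-order metrics that remain informative when thermal noise
#' dominates: skewness and excess kurtosis (non-Gaussianity of the noise
#' distribution — artifact-induced clutter shows up here while staying
#' hidden in tSNR), lag-1 temporal autocorrelation, and the Pearson
#' correlation with the global (mask-mean) signal.
#'
#' Moment maps are computed on the raw time courses by default; the
#' correlation metrics are computed after per-voxel linear detrending by
#' default, since slow drift trivially inflates them. Both choices are
#' switchable.
#'
#' Conventions: skew is the third standardized moment; kurtosis is excess
#' (Gaussian = 0); tSNR is `NA` where the temporal SD is 0.
#'
#' @param ts 4D [voxel_grid] (or array) with at least 3 time points
#'   (4 for kurtosis).
#' @param mask optional logical array; metrics are computed inside it and
#'   the global signal is its mean time course.
#' @param detrend_moments detrending before the moment maps
#'   (`"none"` default, or `"linear"`).
#' @param detrend_corr detrending before autocorrelation / global-signal
#'   correlation (`"linear"` default, or `"none"`).
#' @return list of 3D arrays: `mean`, `stdev`, `tsnr`, `skew`, `kurtosis`,
#'   `lag1_autocorr`, `gs_corr` (`NA` outside the mask).
#' @export
compute_qa_maps <- function(ts, mask = NULL,
                            detrend_moments = c("none", "linear"),
                            detrend_corr = c("linear", "none")) {
  detrend_moments <- match.arg(detrend_moments)
  detrend_corr <- match.arg(detrend_corr)
  grid <- as_voxel_grid(ts)
  d <- dim(grid$data)
  if (length(d) != 4L) stop("'ts' must be a 4D time series")
  nt <- d[4]
  if (nt < 3L) stop("at least 3 time points are required (autocorrelation)")
  if (nt < 4L) warning("kurtosis is unreliable with fewer than 4 points")
  dims <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (inherits(mask, "voxel_grid")) mask <- mask$data != 0
  mask <- array(as.logical(mask) & !is.na(mask), dim = dims)
  if (!any(mask)) stop("mask is empty")

  X <- matrix(grid$data, nrow = prod(dims), ncol = nt)[mask, , drop = FALSE]

  Xm <- if (detrend_moments == "linear") detrend_rows(X) + rowMeans(X) else X
  mu <- rowMeans(Xm)
  cen <- Xm - mu
  m2 <- rowMeans(cen^2)
  m3 <- rowMeans(cen^3)
  m4 <- rowMeans(cen^4)
  stdev <- sqrt(rowSums(cen^2) / (nt - 1))
  skew <- ifelse(m2 > 0, m3 / m2^1.5, NA_real_)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, NA_real_)
  tsnr <- ifelse(stdev > 0, mu / stdev, NA_real_)

  Xc <- if (detrend_corr == "linear") detrend_rows(X) else
    X - rowMeans(X)
  lag1 <- row_cor(Xc[, -nt, drop = FALSE], Xc[, -1, drop = FALSE])
  gs <- colMeans(Xc)
  gsm <- matrix(gs, nrow = nrow(Xc), ncol = nt, byrow = TRUE)
  gscor <- row_cor(Xc, gsm)

  pack <- function(v) {
    out <- array(NA_real_, dim = dims)
    out[mask] <- v
    out
  }
  list(mean = pack(mu), stdev = pack(stdev), tsnr = pack(tsnr),
       skew = pack(skew), kurtosis = pack(kurt),
       lag1_autocorr = pack(lag1), gs_corr = pack(gscor))
}

# remove per-row linear trend (returns zero-mean residuals)
detrend_rows <- function(X) {
  nt <- ncol(X)
  t0 <- seq_len(nt) - (nt + 1) / 2
  beta <- (X %*% t0) / sum(t0^2)
  X - rowMeans(X) - beta %*% t(t0)
}

# rowwise Pearson correlation of two equally shaped matrices
row_cor <- function(A, B) {
  A <- A - rowMeans(A)
  B <- B - rowMeans(B)
  num <- rowSums(A * B)
  den <- sqrt(rowSums(A^2) * rowSums(B^2))
  ifelse(den > 0, pmin(pmax(num / den, -1), 1), NA_real_)
}

#' 3D spatiotemporal noise kernel
#'
#' For every voxel pair at lattice offset `o` with infinity-norm at most
#' `radius`, accumulates the Pearson correlation of the two (optionally
#' detrended) time courses and averages over all in-mask pairs, producing a
#' `(2r+1)^3` volume of mean neighbor correlations with the self-
#' correlation (exactly 1) at the center. The full kernel is returned as a
#' volume rather than summarized by an FWHM, so negative sidelobes,
#' anticorrelations, odd/even saw-tooth patterns and diagonal structure
#' remain visible.
#'
#' @param ts 4D [voxel_grid] (or array), `nt >= 3`.
#' @param radius kernel radius in voxels (default 5, i.e. an 11^3 window).
#' @param mask optional logical array of voxels to include.
#' @param detrend `"linear"` (default) or `"none"` per-voxel detrending
#'   before correlating.
#' @return a [voxel_grid] of shape `(2r+1)^3` (third extent 1 for
#'   single-slice input); offsets with no valid pair are `NA`.
#' @export
compute_noise_kernel <- function(ts, radius = 5, mask = NULL,
                                 detrend = c("linear", "none")) {
  detrend <- match.arg(detrend)
  grid <- as_voxel_grid(ts)
  d <- dim(grid$data)
  if (length(d) != 4L) stop("'ts' must be a 4D time series")
  nt <- d[4]
  if (nt < 3L) stop("at least 3 time points are required")
  dims <- d[1:3]
  radius <- as.integer(radius)
  if (radius < 1) stop("'radius' must be >= 1 voxel")
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (inherits(mask, "voxel_grid")) mask <- mask$data != 0
  mask <- array(as.logical(mask) & !is.na(mask), dim = dims)
  if (!any(mask)) stop("mask is empty")

  X <- matrix(grid$data, nrow = prod(dims), ncol = nt)
  Xc <- if (detrend == "linear") detrend_rows(X) else X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  ok <- mask & array(nrm > 0, dim = dims)
  Xc <- Xc / pmax(nrm, .Machine$double.eps)  # unit-norm rows

  Z <- array(Xc, dim = c(dims, nt))
  okn <- array(as.numeric(ok), dim = dims)

  rz <- if (dims[3] > 1) radius else 0L
  kdim <- c(2L * radius + 1L, 2L * radius + 1L, 2L * rz + 1L)
  kernel <- array(NA_real_, dim = kdim)

  for (oz in -rz:rz) for (oy in -radius:radius) for (ox in -radius:radius) {
    # overlap of the volume with itself shifted by (ox, oy, oz)
    a <- idx_range(dims[1], ox); b <- idx_range(dims[2], oy)
    cc <- idx_range(dims[3], oz)
    if (!length(a$src) || !length(b$src) || !length(cc$src)) next
    m_pair <- ok[a$src, b$src, cc$src, drop = FALSE] &
      ok[a$dst, b$dst, cc$dst, drop = FALSE]
    npair <- sum(m_pair)
    if (npair == 0) next
    s <- 0
    for (t in seq_len(nt)) {
      s <- s + sum((Z[a$src, b$src, cc$src, t] *
                    Z[a$dst, b$dst, cc$dst, t])[m_pair])
    }
    kernel[ox + radius + 1L, oy + radius + 1L, oz + rz + 1L] <- s / npair
  }
  kernel[radius + 1L, radius + 1L, rz + 1L] <- 1
  voxel_grid(kernel, voxel_size = grid$voxel_size)
}

idx_range <- function(n, off) {
  if (off >= 0) list(src = seq_len(n - off), dst = seq_len(n - off) + off)
  else list(src = seq_len(n + off) - off, dst = seq_len(n + off))
}
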