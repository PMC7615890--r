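#' Split an interleaved VASO series into nulled and BOLD series
#'
#' SS-SI-VASO acquires blood-nulled (T1-weighted) and not-nulled
#' (T2*-weighted, BOLD) volumes in alternation. This separates them into
#' two series of half length, each carrying its acquisition timestamps
#' (`k * tr_pair + offset`, with the two contrasts `tr_pair/2` apart).
#'
#' @param series 4D [voxel_grid] (or array) with an even number of volumes
#'   (`nt >= 4`).
#' @param phase `"nulled-first"` (volume 0 is blood-nulled) or
#'   `"bold-first"`.
#' @param tr_pair pair repetition time in seconds; defaults to
#'   `2 * tr` of the series when available.
#' @param timestamps optional explicit length-`nt` vector of acquisition
#'   times in seconds (covers variable-TR acquisitions); overrides
#'   `tr_pair` spacing.
#' @return list of two [voxel_grid]s, `nulled` and `bold`, each with a
#'   numeric attribute `timestamps`.
#' @export
split_interleaved <- function(series, phase = c("nulled-first",
                                                "bold-first"),
                              tr_pair = NULL, timestamps = NULL) {
  phase <- match.arg(phase)
  grid <- as_voxel_grid(series)
  d <- dim(grid$data)
  if (length(d) != 4L) stop("'series' must be a 4D time series")
  nt <- d[4]
  if (nt < 4L) stop("need at least 4 volumes (2 pairs)")
  if (nt %% 2L != 0L)
    stop("odd number of volumes (", nt, "): trim the leading or trailing ",
         "volume so nulled and BOLD counts match")
  if (is.null(tr_pair))
    tr_pair <- if (!is.null(grid$tr) && grid$tr > 0) 2 * grid$tr else 2
  if (is.null(timestamps)) timestamps <- (seq_len(nt) - 1) * tr_pair / 2
  if (length(timestamps) != nt)
    stop("'timestamps' must have one entry per volume")

  odd <- seq(1L, nt, by = 2L)   # volumes 0, 2, 4, ... (0-based even)
  even <- seq(2L, nt, by = 2L)
  first <- grid$data[, , , odd, drop = FALSE]
  second <- grid$data[, , , even, drop = FALSE]
  if (phase == "nulled-first") {
    nulled <- first; bold <- second
    t_n <- timestamps[odd]; t_b <- timestamps[even]
  } else {
    nulled <- second; bold <- first
    t_n <- timestamps[even]; t_b <- timestamps[odd]
  }
  gn <- voxel_grid(nulled, voxel_size = grid$voxel_size, tr = tr_pair,
                   affine = grid$affine)
  gb <- voxel_grid(bold, voxel_size = grid$voxel_size, tr = tr_pair,
                   affine = grid$affine)
  attr(gn, "timestamps") <- t_n
  attr(gb, "timestamps") <- t_b
  list(nulled = gn, bold = gb)
}

#' Temporally align the BOLD series onto the nulled time grid
#'
#' Linearly interpolates every voxel's BOLD time course to the nulled
#' acquisition times, so each nulled volume has a simultaneous BOLD
#' estimate; endpoints are held (nearest extrapolation). The nulled series
#' is the contrast of interest and is left untouched.
#'
#' @param nulled,bold the two series from [split_interleaved()] (their
#'   `timestamps` attributes are used unless given explicitly).
#' @param t_nulled,t_bold optional explicit timestamp vectors (seconds).
#' @param method interpolation method; only `"linear"` is implemented.
#' @return list `nulled` (unchanged) and `bold` (resampled onto the nulled
#'   grid, timestamps updated).
#' @export
temporal_align <- function(nulled, bold, t_nulled = NULL, t_bold = NULL,
                           method = "linear") {
  method <- match.arg(method, "linear")
  gn <- as_voxel_grid(nulled)
  gb <- as_voxel_grid(bold)
  if (is.null(t_nulled)) t_nulled <- attr(nulled, "timestamps")
  if (is.null(t_bold)) t_bold <- attr(bold, "timestamps")
  if (is.null(t_nulled) || is.null(t_bold))
    stop("timestamps unknown; pass t_nulled / t_bold")
  dn <- dim(gn$data); db <- dim(gb$data)
  if (length(dn) != 4L || length(db) != 4L ||
      !identical(dn[1:3], db[1:3]))
    stop("nulled and bold must be 4D series on the same lattice")
  if (length(t_nulled) != dn[4] || length(t_bold) != db[4])
    stop("timestamp lengths do not match the series")

  # linear interpolation is a fixed linear map of the bold frames: build
  # the weights once and apply them to the whole (nvox x nt) matrix
  nb <- db[4]
  i_hi <- findInterval(t_nulled, t_bold, all.inside = TRUE)
  t_lo <- t_bold[i_hi]; t_hi <- t_bold[i_hi + 1L]
  w_hi <- (t_nulled - t_lo) / (t_hi - t_lo)
  w_hi <- pmin(pmax(w_hi, 0), 1)  # endpoint hold
  B <- matrix(gb$data, nrow = prod(db[1:3]), ncol = nb)
  out <- B[, i_hi, drop = FALSE] * rep(1 - w_hi, each = nrow(B)) +
    B[, i_hi + 1L, drop = FALSE] * rep(w_hi, each = nrow(B))
  gba <- voxel_grid(array(out, dim = c(dn[1:3], dn[4])),
                    voxel_size = gb$voxel_size, tr = gn$tr,
                    affine = gb$affine)
  attr(gn, "timestamps") <- t_nulled
  attr(gba, "timestamps") <- t_nulled
  list(nulled = gn, bold = gba)
}

#' BOLD correction of VASO by dynamic division
#'
#' BOLD contamination of the blood-nulled series is multiplicative (T1 and
#' T2* relaxation act as independent factors), so it is removed by
#' dividing the nulled series by the time-aligned BOLD series:
#' `vaso = nulled / bold`. Divisions by values at or below `eps` times the
#' series mean yield `NA` and are flagged rather than propagated as
#' infinities. Optionally the result is clipped to
#' `[0, clip_max * voxel-mean]`, which must be requested explicitly
#' (division blow-ups at vessel voxels are common in practice).
#'
#' The resulting VASO time course is anti-correlated with BOLD under
#' activation: BOLD rises where VASO falls.
#'
#' @param nulled,bold_aligned 4D series on a common time grid (see
#'   [temporal_align()]).
#' @param clip_max clip ceiling in units of the voxel's mean VASO value,
#'   or `NULL` (default) for no clipping.
#' @param eps guard threshold as a fraction of the BOLD series mean.
#' @return a [voxel_grid] of the VASO series; flagged samples are recorded
#'   in the logical attribute `flagged` (4D array).
#' @export
boco <- function(nulled, bold_aligned, clip_max = NULL, eps = 1e-9) {
  gn <- as_voxel_grid(nulled)
  gb <- as_voxel_grid(bold_aligned)
  if (!identical(dim(gn$data), dim(gb$data)))
    stop("nulled and aligned BOLD series differ in shape")
  thr <- eps * mean(abs(gb$data))
  bad <- !is.finite(gb$data) | abs(gb$data) <= thr
  vaso <- gn$data / gb$data
  vaso[bad] <- NA_real_
  if (!is.null(clip_max)) {
    d <- dim(vaso)
    V <- matrix(vaso, nrow = prod(d[1:3]), ncol = d[4])
    vm <- rowMeans(V, na.rm = TRUE)
    hi <- clip_max * vm
    V <- pmin(pmax(V, 0), matrix(hi, nrow = length(vm), ncol = d[4]))
    vaso <- array(V, dim = d)
  }
  out <- voxel_grid(vaso, voxel_size = gn$voxel_size, tr = gn$tr,
                    affine = gn$affine)
  attr(out, "timestamps") <- attr(nulled, "timestamps")
  attr(out, "flagged") <- bad
  out
}

#' Full VASO BOLD-correction pipeline
#'
#' [split_interleaved()], [temporal_align()] and [boco()] in one call.
#'
#' @inheritParams split_interleaved
#' @inheritParams boco
#' @return list `nulled`, `bold` (aligned), `vaso`.
#' @export
boco_pipeline <- function(series, phase = "nulled-first", tr_pair = NULL,
                          timestamps = NULL, clip_max = NULL) {
  sp <- split_interleaved(series, phase = phase, tr_pair = tr_pair,
                          timestamps = timestamps)
  al <- temporal_align(sp$nulled, sp$bold)
  list(nulled = al$nulled, bold = al$bold,
       vaso = boco(al$nulled, al$bold, clip_max = clip_max))
}
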