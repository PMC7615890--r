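#' Generate a rim-coded phantom with analytic ground truth
#'
#' Deterministic geometric phantoms for testing and demonstration. All
#' geometries are built from signed distances to analytic surfaces, so the
#' returned ground-truth maps (`truth$equidist`, plus the closed-form
#' equal-area radius for the annulus) are exact up to voxelization.
#'
#' Geometries:
#' * `flat_slab`: a slab normal to `normal_axis` with `thickness` GM voxels
#'   between one-voxel code-1 (inner) and code-2 (outer) borders. Zero
#'   curvature: the equi-volume metric must equal the equi-distant one.
#' * `annulus_2d`: a single-slice ring, GM between radii `r1` and `r2`
#'   (voxels), code 1 on the inner rim and code 2 on the outer rim (swap
#'   with `swap_borders` for a sulcus-like geometry). The closed-form
#'   equal-area radius is `sqrt((r1^2 + r2^2) / 2)`.
#' * `sine_wall_3d`: a folded cortical wall `z = z0 + amp * sin(2*pi*x /
#'   wavelength)` extruded along y, with GM `thickness` voxels thick.
#' * `kissing_gyri`: two parallel slabs whose outer borders face each other
#'   across a `gap`-voxel code-0 gap — Euclidean-near but geodesically
#'   disconnected, the adversarial case for smoothing and growing.
#'
#' @param geometry one of `"flat_slab"`, `"annulus_2d"`, `"sine_wall_3d"`,
#'   `"kissing_gyri"`.
#' @param shape integer length-3 volume shape (the annulus forces
#'   `shape[3] = 1`).
#' @param thickness GM thickness in voxels (slab / wall / kissing gyri).
#' @param r1,r2 inner and outer GM radii in voxels (annulus; `r2 > r1`).
#' @param amp,wavelength sine-wall fold amplitude and wavelength in voxels.
#' @param gap code-0 gap width in voxels between the kissing slabs.
#' @param normal_axis slab normal axis (1, 2 or 3).
#' @param swap_borders swap codes 1 and 2 (annulus: turns the gyrus-like
#'   ring into a sulcus-like one).
#' @param voxel_size voxel size in mm.
#' @return list with `rim` (a rim-coded [voxel_grid]) and `truth` (a list
#'   with analytic maps; contents depend on geometry).
#' @export
make_rim_phantom <- function(geometry = c("flat_slab", "annulus_2d",
                                          "sine_wall_3d", "kissing_gyri"),
                             shape = c(16, 16, 16), thickness = 6,
                             r1 = 20, r2 = 40, amp = 6, wavelength = 32,
                             gap = 1, normal_axis = 3, swap_borders = FALSE,
                             voxel_size = c(1, 1, 1)) {
  geometry <- match.arg(geometry)
  shape <- as.integer(shape)
  out <- switch(geometry,
    flat_slab = phantom_flat_slab(shape, thickness, normal_axis),
    annulus_2d = phantom_annulus(shape, r1, r2),
    sine_wall_3d = phantom_sine_wall(shape, thickness, amp, wavelength),
    kissing_gyri = phantom_kissing(shape, thickness, gap))
  if (swap_borders) {
    a <- out$codes
    a[out$codes == 1] <- 2
    a[out$codes == 2] <- 1
    out$codes <- a
    if (!is.null(out$truth$equidist))
      out$truth$equidist <- 1 - out$truth$equidist
  }
  list(rim = voxel_grid(out$codes, voxel_size = voxel_size),
       truth = out$truth)
}

phantom_flat_slab <- function(shape, thickness, normal_axis) {
  if (thickness < 1) stop("slab thickness must be >= 1 voxel")
  n <- shape[normal_axis]
  if (n < thickness + 4)
    stop("shape along the normal axis too small for the slab")
  codes1d <- integer(n)
  p <- max(1L, (n - thickness - 2L) %/% 2L)  # leading code-0 pad
  codes1d[p + 1L] <- 1L
  codes1d[p + 1L + seq_len(thickness)] <- 3L
  codes1d[p + 2L + thickness] <- 2L
  eq1d <- rep(NA_real_, n)
  eq1d[p + 1L + seq_len(thickness)] <- seq_len(thickness) / (thickness + 1)
  codes <- array(0L, dim = shape)
  truth_eq <- array(NA_real_, dim = shape)
  idx <- slice_index(shape, normal_axis)
  for (k in seq_len(n)) {
    codes[idx(k)] <- codes1d[k]
    truth_eq[idx(k)] <- eq1d[k]
  }
  list(codes = codes, truth = list(equidist = truth_eq,
                                   gm_rows = p + 1L + seq_len(thickness),
                                   normal_axis = normal_axis))
}

slice_index <- function(shape, axis) {
  function(k) {
    ii <- lapply(seq_along(shape), function(a)
      if (a == axis) k else seq_len(shape[a]))
    as.matrix(expand.grid(ii))
  }
}

phantom_annulus <- function(shape, r1, r2) {
  if (r2 <= r1) stop("outer radius must exceed inner radius")
  nx <- shape[1]; ny <- shape[2]
  if (min(nx, ny) < 2 * (r2 + 2))
    stop("shape too small for annulus of outer radius ", r2)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny) - cx
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy
  r <- sqrt(x^2 + y^2)
  codes <- matrix(0L, nx, ny)
  codes[r >= r1 - 1 & r < r1] <- 1L
  codes[r >= r1 & r < r2] <- 3L
  codes[r >= r2 & r < r2 + 1] <- 2L
  eq <- matrix(NA_real_, nx, ny)
  gm <- codes == 3L
  eq[gm] <- (r[gm] - r1) / (r2 - r1)
  dim(codes) <- c(nx, ny, 1L)
  dim(eq) <- c(nx, ny, 1L)
  list(codes = codes,
       truth = list(equidist = eq, radius = array(r, dim = c(nx, ny, 1L)),
                    equal_area_radius = sqrt((r1^2 + r2^2) / 2),
                    r1 = r1, r2 = r2))
}

phantom_sine_wall <- function(shape, thickness, amp, wavelength) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  z0 <- (nz - thickness) / 2 - amp
  if (z0 < 2 || z0 + 2 * amp + thickness + 2 > nz - 1)
    stop("shape[3] too small for the sine wall")
  codes <- array(0L, dim = shape)
  f <- z0 + amp + amp * sin(2 * pi * seq_len(nx) / wavelength)
  for (ix in seq_len(nx)) {
    zb <- round(f[ix])
    codes[ix, , zb] <- 1L
    codes[ix, , zb + seq_len(thickness)] <- 3L
    codes[ix, , zb + thickness + 1L] <- 2L
  }
  list(codes = codes, truth = list(base = f, thickness = thickness))
}

phantom_kissing <- function(shape, thickness, gap) {
  n3 <- shape[3]
  need <- 2 * (thickness + 2) + gap + 2
  if (n3 < need) stop("shape[3] must be at least ", need)
  codes <- array(0L, dim = shape)
  p <- (n3 - need + 2) %/% 2
  # slab A: code1, GM, code2 (outer border faces the gap)
  codes[, , p + 1L] <- 1L
  codes[, , p + 1L + seq_len(thickness)] <- 3L
  codes[, , p + 2L + thickness] <- 2L
  top <- p + 2L + thickness + gap
  # slab B mirrored: code2 faces the gap
  codes[, , top + 1L] <- 2L
  codes[, , top + 1L + seq_len(thickness)] <- 3L
  codes[, , top + 2L + thickness] <- 1L
  list(codes = codes,
       truth = list(slab_a_gm = p + 1L + seq_len(thickness),
                    slab_b_gm = top + 1L + seq_len(thickness),
                    gap = (p + 3L + thickness):(top)))
}

#' Generate synthetic 4D noise series
#'
#' Seed-deterministic generators for the noise regimes the QA metrics are
#' designed to detect.
#'
#' Models:
#' * `white`: i.i.d. Gaussian, mean `baseline`, SD `sigma` — the
#'   thermal-noise-dominated regime.
#' * `ar1_time`: temporal AR(1) per voxel with coefficient `phi`
#'   (stationary; lag-1 autocorrelation `phi`).
#' * `ar1_spatial`: AR(1) coupling along the x axis between neighboring
#'   voxels (neighbor correlation `phi`), independent across y, z and time
#'   — spatial noise coupling as produced by readout-related leakage.
#' * `smoothed`: white noise smoothed spatially with a Gaussian of SD
#'   `smooth_sigma` voxels per frame.
#' * `artifact_clutter`: white noise plus a strongly skewed (squared
#'   Gaussian) component of SD comparable to the noise floor inside a
#'   central region — clutter that skew/kurtosis maps detect but tSNR
#'   hides.
#'
#' @param shape spatial shape (length 3).
#' @param nt number of time points (>= 3).
#' @param model one of the models above.
#' @param phi AR(1) coefficient (`ar1_time`, `ar1_spatial`).
#' @param smooth_sigma spatial Gaussian SD in voxels (`smoothed`).
#' @param baseline,sigma mean level and noise SD.
#' @param tr repetition time in seconds.
#' @param seed RNG seed (integer); reruns are bit-identical.
#' @return a 4D [voxel_grid]; for `artifact_clutter` the clutter region
#'   mask is attached as attribute `clutter_mask`.
#' @export
make_noise_series <- function(shape, nt, model = c("white", "ar1_time",
                                                   "ar1_spatial",
                                                   "smoothed",
                                                   "artifact_clutter"),
                              phi = 0.5, smooth_sigma = 1,
                              baseline = 100, sigma = 10, tr = 2,
                              seed = 1) {
  model <- match.arg(model)
  if (nt < 3) stop("nt must be >= 3")
  shape <- as.integer(shape)
  nvox <- prod(shape)
  set.seed(seed)
  eps <- array(rnorm(nvox * nt), dim = c(shape, nt))
  clutter_mask <- NULL
  x <- switch(model,
    white = eps,
    ar1_time = {
      out <- eps
      out[, , , 1] <- eps[, , , 1]
      for (t in 2:nt)
        out[, , , t] <- phi * out[, , , t - 1] +
          sqrt(1 - phi^2) * eps[, , , t]
      out
    },
    ar1_spatial = {
      out <- eps
      if (shape[1] > 1)
        for (i in 2:shape[1])
          out[i, , , ] <- phi * out[i - 1, , , ] +
            sqrt(1 - phi^2) * eps[i, , , ]
      out
    },
    smoothed = {
      out <- eps
      for (t in seq_len(nt))
        out[, , , t] <- gauss_smooth_sep(array(eps[, , , t], dim = shape),
                                         smooth_sigma)
      out
    },
    artifact_clutter = {
      ctr <- lapply(shape, function(n) {
        lo <- max(1L, n %/% 4L); hi <- min(n, lo + max(1L, n %/% 4L))
        lo:hi
      })
      m <- array(FALSE, dim = shape)
      m[ctr[[1]], ctr[[2]], ctr[[3]]] <- TRUE
      clutter_mask <- m
      g <- array(rnorm(nvox * nt), dim = c(shape, nt))
      clut <- (g^2 - 1) / sqrt(2)  # zero-mean, unit-SD, skew 2*sqrt(2)
      out <- eps
      for (t in seq_len(nt)) {
        fr <- out[, , , t]
        fr[m] <- (eps[, , , t][m] + clut[, , , t][m]) / sqrt(2)
        out[, , , t] <- fr
      }
      out
    })
  g <- voxel_grid(baseline + sigma * x, tr = tr)
  attr(g, "clutter_mask") <- clutter_mask
  g
}

# separable Gaussian smoothing of a 3D array (reflecting edges not needed
# for the synthetic use: zero-padded convolution normalized by kernel mass)
gauss_smooth_sep <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(a)
  for (axis in 1:3) {
    if (d[axis] == 1) next
    out <- array(0, dim = d)
    for (o in seq(-r, r)) {
      off <- c(0L, 0L, 0L); off[axis] <- o
      out <- out + k[o + r + 1] * shift_array_num(a, off)
    }
    a <- out
  }
  a
}

#' Generate an interleaved VASO run with ground truth
#'
#' Forward-simulates the SS-SI-VASO acquisition: a blood-nulled
#' (T1-weighted) series and a not-nulled (BOLD, T2*-weighted) series
#' acquired in alternation. BOLD contamination is multiplicative, so the
#' nulled samples are `v(t) * b(t)` at the nulled timestamps and the BOLD
#' samples are `b(t)` at the bold timestamps. The task design is a block
#' paradigm with raised-cosine ramps (approximating hemodynamic rise/fall),
#' so the signals are smooth enough that linear temporal alignment is
#' interpolation-limited.
#'
#' @param shape spatial shape (default a single voxel-thick patch).
#' @param n_pairs number of nulled/bold volume pairs.
#' @param tr_pair pair repetition time in seconds (one nulled + one bold
#'   acquisition); the two contrasts are `tr_pair/2` apart.
#' @param vaso_amp relative VASO signal change under task (negative:
#'   blood-volume increase darkens VASO; default -0.02).
#' @param bold_amp relative BOLD signal change under task (default +0.05).
#' @param block_s on/off block duration in seconds.
#' @param ramp_s raised-cosine transition duration in seconds.
#' @param noise_sd SD of additive Gaussian noise on the acquired samples
#'   (relative units; default 0 = noiseless ground-truth run).
#' @param phase `"nulled-first"` (even volumes nulled) or `"bold-first"`.
#' @param seed RNG seed for the noise.
#' @return list: `series` (interleaved 4D [voxel_grid], `tr = tr_pair/2`),
#'   `tr_pair`, `phase`, `v_fun`/`b_fun` (ground-truth signal functions of
#'   time in seconds), `t_nulled`, `t_bold`.
#' @export
make_vaso_run <- function(shape = c(4, 4, 1), n_pairs = 100, tr_pair = 2,
                          vaso_amp = -0.02, bold_amp = 0.05,
                          block_s = 20, ramp_s = 8, noise_sd = 0,
                          phase = c("nulled-first", "bold-first"),
                          seed = 1) {
  phase <- match.arg(phase)
  box <- function(t) {
    u <- t %% (2 * block_s)
    y <- numeric(length(t))
    ru <- u < ramp_s
    y[ru] <- 0.5 * (1 - cos(pi * u[ru] / ramp_s))
    on <- u >= ramp_s & u < block_s
    y[on] <- 1
    rd <- u >= block_s & u < block_s + ramp_s
    y[rd] <- 0.5 * (1 + cos(pi * (u[rd] - block_s) / ramp_s))
    y
  }
  v_fun <- function(t) 1 + vaso_amp * box(t)
  b_fun <- function(t) 1 + bold_amp * box(t)

  off <- if (phase == "nulled-first") c(0, tr_pair / 2) else
    c(tr_pair / 2, 0)
  t_nulled <- (seq_len(n_pairs) - 1) * tr_pair + off[1]
  t_bold <- (seq_len(n_pairs) - 1) * tr_pair + off[2]

  nvox <- prod(shape)
  nt <- 2L * n_pairs
  dat <- array(0, dim = c(shape, nt))
  set.seed(seed)
  nulled_vals <- v_fun(t_nulled) * b_fun(t_nulled)
  bold_vals <- b_fun(t_bold)
  for (k in seq_len(n_pairs)) {
    nv <- nulled_vals[k] + rnorm(nvox, sd = noise_sd)
    bv <- bold_vals[k] + rnorm(nvox, sd = noise_sd)
    if (phase == "nulled-first") {
      dat[, , , 2 * k - 1] <- nv
      dat[, , , 2 * k] <- bv
    } else {
      dat[, , , 2 * k - 1] <- bv
      dat[, , , 2 * k] <- nv
    }
  }
  list(series = voxel_grid(dat, tr = tr_pair / 2),
       tr_pair = tr_pair, phase = phase,
       v_fun = v_fun, b_fun = b_fun,
       t_nulled = t_nulled, t_bold = t_bold)
}

#' Generate a leaky laminar toy volume with ground truth
#'
#' Forward model of ascending-vein signal leakage: per column, the measured
#' K-layer profile is `S = A %*% m + noise`, with `A` the unit-lower-
#' triangular leakage matrix built from the CBVv depth profile. Profiles
#' are broadcast into a toy volume with layers stacked along z (deepest at
#' z = 1) and columns along x.
#'
#' @param K number of layers.
#' @param m true microvascular profiles: length-K vector (recycled) or
#'   K x n_columns matrix.
#' @param cbv length-K venous blood volume weights (> 0), deep first.
#' @param n_columns number of columns along x.
#' @param noise_sd SD of i.i.d. Gaussian noise added to each voxel.
#' @param seed RNG seed.
#' @return list: `vol` ([voxel_grid] `n_columns` x 1 x K), `layer_id` and
#'   `column_id` integer arrays, `truth` (matrix of true `m`), `model`
#'   (the [build_leakage_model()] output).
#' @export
make_leaky_volume <- function(K, m, cbv, n_columns = 1, noise_sd = 0,
                              seed = 1) {
  if (K < 2) stop("K must be >= 2")
  model <- build_leakage_model(cbv)
  m <- if (is.matrix(m)) m else matrix(m, nrow = K, ncol = n_columns)
  if (nrow(m) != K || ncol(m) != n_columns)
    stop("'m' must be K x n_columns")
  set.seed(seed)
  S <- model$A %*% m + matrix(rnorm(K * n_columns, sd = noise_sd), K)
  vol <- array(0, dim = c(n_columns, 1L, K))
  layer_id <- array(0L, dim = c(n_columns, 1L, K))
  column_id <- array(0L, dim = c(n_columns, 1L, K))
  for (k in seq_len(K)) {
    vol[, 1, k] <- S[k, ]
    layer_id[, 1, k] <- k
    column_id[, 1, k] <- seq_len(n_columns)
  }
  list(vol = voxel_grid(vol), layer_id = layer_id, column_id = column_id,
       truth = m, model = model)
}
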