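#' Build an ascending-vein leakage model from a CBVv depth profile
#'
#' Layer profiles are ordered deep to superficial (index 1 = deepest).
#' The measured GE-BOLD signal of a layer is modelled as the layer's own
#' microvascular response plus a weighted sum of the responses of all
#' deeper layers, carried up by ascending veins. With venous blood volume
#' weights `c_k > 0` per layer, the mixing matrix is unit-lower-triangular
#' with `A[i, j] = c_j / c_i` for `i > j` (deeper layer `j` leaks into
#' layer `i` in proportion to relative venous volume), and the scaling
#' vector for the gain model is `s_k = c_k / mean(c)`. With uniform CBVv
#' the leakage operator reduces to a pure cumulative sum and `s == 1`.
#'
#' @param cbv numeric vector of K venous blood volume weights, deep first,
#'   all strictly positive.
#' @return object of class `leakage_model`: `A` (K x K unit-lower-
#'   triangular), `s` (length K), `cbv`, `K`.
#' @export
build_leakage_model <- function(cbv) {
  cbv <- as.numeric(cbv)
  K <- length(cbv)
  if (K < 1 || any(!is.finite(cbv)) || any(cbv <= 0))
    stop("all CBVv weights must be strictly positive")
  A <- diag(1, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i > j) A[i, j] <- cbv[j] / cbv[i]
  }
  structure(list(A = A, s = cbv / mean(cbv), cbv = cbv, K = K),
            class = "leakage_model")
}

#' @export
print.leakage_model <- function(x, ...) {
  cat("<leakage_model> K =", x$K, "layers; scaling s =",
      paste(format(x$s, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

check_profile <- function(profile, K) {
  profile <- as.numeric(profile)
  if (length(profile) != K)
    stop("profile length ", length(profile), " does not match K = ", K)
  profile
}

#' Remove inter-layer leakage by triangular deconvolution
#'
#' Inverts the leakage mixing `S = A %*% m` by forward substitution
#' (equivalently, consecutive signal subtraction from the deepest layer
#' upward): exact to numerical precision since `A` has unit diagonal.
#'
#' @param profile measured K-layer profile, deep first.
#' @param model a [build_leakage_model()] object.
#' @return the deveined profile `m`.
#' @export
devein_leakage <- function(profile, model) {
  stopifnot(inherits(model, "leakage_model"))
  S <- check_profile(profile, model$K)
  as.numeric(forwardsolve(model$A, S))
}

#' Remove the layer-dependent venous gain by scaling
#'
#' Divides each layer by its venous-volume gain `s_k`: a profile that is a
#' pure gain pattern (`S = alpha * s`) flattens to the constant `alpha`.
#'
#' @inheritParams devein_leakage
#' @return the gain-normalized profile `S / s`.
#' @export
devein_scaling <- function(profile, model) {
  stopifnot(inherits(model, "leakage_model"))
  S <- check_profile(profile, model$K)
  S / model$s
}

#' Remove a linear depth trend from a layer profile
#'
#' Treats the macrovascular bias as a task-independent component linear in
#' depth and subtracts the least-squares linear trend across the layer
#' index; the output has zero mean and zero linear component (the
#' operation is idempotent).
#'
#' @param profile K-layer profile, deep first, `K >= 3`.
#' @return the detrended profile.
#' @export
devein_linear <- function(profile) {
  S <- as.numeric(profile)
  K <- length(S)
  if (K < 3) stop("need at least 3 layers to separate a linear trend")
  x <- seq_len(K) - (K + 1) / 2
  S - mean(S) - sum(S * x) / sum(x^2) * x
}

#' Voxel-wise model-based vein mitigation
#'
#' Applies one of the three deveining models voxel-by-voxel so that the
#' corrected signal stays inspectable as a map across layers and columns:
#' per region (unit column or user ROI), the K-layer profile is extracted
#' as the mean over voxels of each layer, the 1D correction is applied to
#' that profile, and every voxel is then rescaled (leakage and scaling
#' models: multiplied by its layer's correction ratio) or shifted (linear
#' model: its layer's trend value subtracted).
#'
#' The CBVv weights driving the scaling/leakage models can be estimated
#' from GLM residuals: with `cbv = "from-residuals"`, `c_k` is the mean
#' residual standard deviation per layer, normalized to mean 1.
#'
#' @param data 3D volume (or 4D series, corrected frame by frame) as a
#'   [voxel_grid] or array.
#' @param layers layer labels `1..K` (deep first): `layer_metrics` with
#'   `layer_id`, [voxel_grid], or integer array.
#' @param method `"leakage"`, `"CBV"` (scaling) or `"linear"`.
#' @param cbv numeric CBVv weights (deep first), or `"from-residuals"`.
#' @param residuals 4D residual series ([voxel_grid] or array), required
#'   with `cbv = "from-residuals"`.
#' @param roi optional integer array of region labels (e.g. the
#'   `column_id` of [build_unit_columns()]); default treats the labelled
#'   volume as one region.
#' @return a [voxel_grid] with the corrected values (uncorrected voxels,
#'   i.e. those without a layer label, pass through unchanged).
#' @export
devein_voxelwise <- function(data, layers,
                             method = c("leakage", "CBV", "linear"),
                             cbv = NULL, residuals = NULL, roi = NULL) {
  method <- match.arg(method)
  grid <- as_voxel_grid(data)
  dims <- spatial_dim(grid)
  lid <- resolve_layers(layers, dims)
  K <- max(lid)
  if (K < 1) stop("no layer labels found under the data mask")

  if (method != "linear") {
    if (is.null(cbv))
      stop("method '", method, "' needs CBVv weights ",
           "(numeric vector or \"from-residuals\")")
    if (identical(cbv, "from-residuals")) {
      if (is.null(residuals))
        stop("cbv = \"from-residuals\" needs a 'residuals' series")
      rg <- as_voxel_grid(residuals)
      rd <- dim(rg$data)
      if (length(rd) != 4L || !identical(rd[1:3], dims))
        stop("'residuals' must be a 4D series on the data lattice")
      R <- matrix(rg$data, nrow = prod(dims), ncol = rd[4])
      rsd <- sqrt(rowSums((R - rowMeans(R))^2) / (rd[4] - 1))
      cbv <- vapply(seq_len(K), function(k)
        mean(rsd[lid == k]), numeric(1))
      cbv <- cbv / mean(cbv)
    }
    model <- build_leakage_model(cbv)
    if (model$K != K)
      stop("CBVv weights (", model$K, ") do not match the number of ",
           "layers (", K, ")")
  } else model <- NULL

  if (is.null(roi)) {
    roi <- array(0L, dim = dims)
    roi[lid > 0] <- 1L
  }
  if (inherits(roi, "voxel_grid")) roi <- roi$data
  roi <- array(as.integer(roi), dim = dims)
  roi[is.na(roi) | lid == 0L] <- 0L

  d <- dim(grid$data)
  nt <- if (length(d) == 4L) d[4] else 1L
  X <- matrix(grid$data, nrow = prod(dims), ncol = nt)
  out <- X
  for (r in setdiff(unique(as.vector(roi)), 0L)) {
    in_r <- roi == r
    for (t in seq_len(nt)) {
      S <- vapply(seq_len(K), function(k) {
        v <- X[in_r & lid == k, t]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      if (anyNA(S)) next  # region does not span all layers: leave as-is
      corr <- switch(method,
                     leakage = devein_leakage(S, model),
                     CBV = devein_scaling(S, model),
                     linear = devein_linear(S))
      for (k in seq_len(K)) {
        sel <- in_r & lid == k
        if (!any(sel)) next
        if (method == "linear") {
          out[sel, t] <- X[sel, t] - (S[k] - corr[k])
        } else {
          ratio <- if (abs(S[k]) > .Machine$double.eps)
            corr[k] / S[k] else 0
          out[sel, t] <- X[sel, t] * ratio
        }
      }
    }
  }
  voxel_grid(array(out, dim = d), voxel_size = grid$voxel_size,
             tr = grid$tr, affine = grid$affine)
}
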