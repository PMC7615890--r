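#' Grow geodesic cortical depths from a rim volume
#'
#' Computes, for every pure-gray-matter (code 3) voxel, the geodesic
#' distance in mm to the nearest inner (code 1) and outer (code 2) border
#' voxel. Distances are shortest-path lengths on the 26-connected voxel
#' lattice (8-connected for single-slice images) with true Euclidean
#' center-to-center step costs under the grid's (possibly anisotropic)
#' voxel size. Growth from the inner border is confined to codes `{1,3}`
#' and from the outer border to codes `{2,3}`, so distances never leak
#' across the CSF gap between kissing gyri. The border voxel realizing each
#' minimum is recorded (ties resolve to the smallest linear voxel index).
#'
#' @param rim rim-coded [voxel_grid] (codes 0/1/2/3) containing at least
#'   one voxel each of codes 1, 2 and 3.
#' @return an object of class `depth_field`: arrays `d_inner`, `d_outer`,
#'   `thickness` (mm; `NA` outside GM, `Inf` for unreachable GM voxels),
#'   integer arrays `nearest_inner`/`nearest_outer` (1-based linear indices
#'   of the realizing border voxels), logical `gm_mask`, and the voxel size.
#' @export
grow_geodesic_depths <- function(rim) {
  rim <- as_voxel_grid(rim)
  a <- rim$data
  if (length(dim(a)) != 3L) stop("rim must be a single 3D volume")
  codes <- as.integer(a)
  dims <- dim(a)
  if (!any(codes == 1L)) stop("rim contains no code-1 (inner border) voxels")
  if (!any(codes == 2L)) stop("rim contains no code-2 (outer border) voxels")
  if (!any(codes == 3L)) stop("rim contains no code-3 (gray matter) voxels")

  g1 <- grow_geodesic_cpp(codes, dims, rim$voxel_size, 1L, c(1L, 3L))
  g2 <- grow_geodesic_cpp(codes, dims, rim$voxel_size, 2L, c(2L, 3L))

  gm <- codes == 3L
  mk <- function(v) {
    out <- array(NA_real_, dim = dims)
    out[gm] <- v[gm]
    out
  }
  mki <- function(v) {
    out <- array(NA_integer_, dim = dims)
    out[gm] <- v[gm]
    out
  }
  d_inner <- mk(g1$dist)
  d_outer <- mk(g2$dist)
  n_unreach <- sum(!is.finite(d_inner[gm]) | !is.finite(d_outer[gm]))
  if (n_unreach > 0)
    warning(n_unreach, " gray-matter voxel(s) unreachable from a border; ",
            "they carry Inf and are excluded downstream")
  structure(list(d_inner = d_inner, d_outer = d_outer,
                 thickness = d_inner + d_outer,
                 nearest_inner = mki(g1$origin),
                 nearest_outer = mki(g2$origin),
                 gm_mask = array(gm, dim = dims),
                 rim = a,
                 voxel_size = rim$voxel_size),
            class = "depth_field")
}

#' @export
print.depth_field <- function(x, ...) {
  gm <- x$gm_mask & is.finite(x$thickness)
  cat("<depth_field> ", sum(x$gm_mask), " GM voxels; thickness ",
      format(mean(x$thickness[gm]), digits = 4), " mm (mean)\n", sep = "")
  invisible(x)
}

#' Equi-distant cortical depth metric
#'
#' Normalized cortical depth `d_inner / (d_inner + d_outer)`, 0 at the
#' inner (WM-facing) border and 1 at the outer (CSF-facing) border. Voxels
#' with zero thickness (simultaneously on both borders under the growing)
#' are assigned 0.5 and flagged.
#'
#' @param depths a `depth_field` from [grow_geodesic_depths()].
#' @return an object of class `layer_metrics` with array `equidist`
#'   (`NA` outside GM and for unreachable voxels), `gm_mask`, the rim, and
#'   a logical `flat_flag` array marking zero-thickness voxels.
#' @export
compute_equidist <- function(depths) {
  stopifnot(inherits(depths, "depth_field"))
  dims <- dim(depths$d_inner)
  eq <- array(NA_real_, dim = dims)
  ok <- depths$gm_mask & is.finite(depths$thickness)
  flat <- ok & depths$thickness == 0
  pos <- ok & depths$thickness > 0
  eq[pos] <- depths$d_inner[pos] / depths$thickness[pos]
  eq[flat] <- 0.5
  structure(list(equidist = eq, equivol = NULL, layer_id = NULL,
                 gm_mask = depths$gm_mask, flat_flag = flat,
                 rim = depths$rim, voxel_size = depths$voxel_size),
            class = "layer_metrics")
}

#' @export
print.layer_metrics <- function(x, ...) {
  cat("<layer_metrics> ", sum(x$gm_mask), " GM voxels; equidist ",
      if (is.null(x$equidist)) "-" else "ok", ", equivol ",
      if (is.null(x$equivol)) "-" else "ok", ", layers ",
      if (is.null(x$layer_id)) "-" else max(x$layer_id, na.rm = TRUE),
      "\n", sep = "")
  invisible(x)
}

#' Build unit columns from streamlines
#'
#' Each gray-matter voxel's streamline is the pair of border voxels nearest
#' to it (`nearest_inner`, `nearest_outer`). Voxels sharing a
#' `nearest_outer` anchor form the initial columns — the thinnest
#' exhaustive partition with one column per touched outer-border voxel.
#' Columns without inner contact (no member voxel 26-adjacent to a code-1
#' voxel) are then merged downhill: the member with smallest `d_inner`
#' donates its column to the column of its steepest-descent gray-matter
#' neighbor, so every final column touches at least one inner and one outer
#' border voxel. Curvature class per column follows from counting the
#' unique border voxels its streamlines connect to: more outer than inner
#' contacts = gyrus, fewer = sulcus, equal = straight.
#'
#' @param rim rim-coded [voxel_grid].
#' @param depths matching `depth_field`.
#' @return an object of class `unit_columns`: integer array `column_id`
#'   (`NA` outside GM / unreachable) and a data frame `columns` with
#'   `column_id`, `n_members`, `n_inner_touched`, `n_outer_touched`,
#'   `curvature_class`.
#' @export
build_unit_columns <- function(rim, depths) {
  rim <- as_voxel_grid(rim)
  stopifnot(inherits(depths, "depth_field"))
  dims <- dim(rim$data)
  codes <- as.integer(rim$data)
  gm_ok <- which(depths$gm_mask & is.finite(depths$thickness))

  anchor <- depths$nearest_outer[gm_ok]
  col_of_anchor <- match(anchor, sort(unique(anchor)))
  column_id <- array(NA_integer_, dim = dims)
  column_id[gm_ok] <- col_of_anchor

  # inner contact: voxel 26-adjacent to a code-1 voxel
  adj1 <- adjacent_to_code(codes, dims, 1L)
  d_inner_v <- depths$d_inner

  repeat {
    ids <- column_id[gm_ok]
    has_contact <- tapply(adj1[gm_ok], ids, any)
    stubs <- as.integer(names(has_contact))[!has_contact]
    if (length(stubs) == 0) break
    changed <- FALSE
    for (s in stubs) {
      mem <- gm_ok[ids == s]
      v <- mem[which.min(d_inner_v[mem])]
      nb <- neighbors26(v, dims)
      nb <- nb[!is.na(column_id[nb]) & column_id[nb] != s]
      if (length(nb) == 0) next
      nb <- nb[d_inner_v[nb] < d_inner_v[v]]
      if (length(nb) == 0) next
      tgt <- column_id[nb[which.min(d_inner_v[nb])]]
      column_id[mem] <- tgt
      changed <- TRUE
    }
    if (!changed) break  # isolated stubs (e.g. enclosed blobs) stay as-is
  }

  # renumber compactly and summarize
  ids <- column_id[gm_ok]
  column_id[gm_ok] <- match(ids, sort(unique(ids)))
  ids <- column_id[gm_ok]
  ni <- tapply(depths$nearest_inner[gm_ok], ids,
               function(x) length(unique(x)))
  no <- tapply(depths$nearest_outer[gm_ok], ids,
               function(x) length(unique(x)))
  nm <- tapply(ids, ids, length)
  cls <- ifelse(no > ni, "gyrus", ifelse(ni > no, "sulcus", "straight"))
  structure(list(column_id = column_id,
                 columns = data.frame(column_id = as.integer(names(nm)),
                                      n_members = as.integer(nm),
                                      n_inner_touched = as.integer(ni),
                                      n_outer_touched = as.integer(no),
                                      curvature_class = unname(cls))),
            class = "unit_columns")
}

#' @export
print.unit_columns <- function(x, ...) {
  cat("<unit_columns> ", nrow(x$columns), " columns over ",
      sum(x$columns$n_members), " GM voxels (",
      paste(names(table(x$columns$curvature_class)),
            table(x$columns$curvature_class), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# logical vector: voxel has a 26-neighbor with the given code
adjacent_to_code <- function(codes, dims, code) {
  a <- array(codes == code, dim = dims)
  out <- array(FALSE, dim = dims)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift_array(a, c(dx, dy, dz), fill = FALSE)
  }
  as.vector(out)
}

# shift array contents by an integer offset, filling exposed edges
shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - off[k]
    i[i < 1 | i > d[k]] <- NA
    i
  })
  out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out[is.na(out)] <- fill
  dim(out) <- d
  out
}

neighbors26 <- function(v, dims) {
  ijk <- lin_to_ijk(v, dims)
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    p <- ijk + c(dx, dy, dz)
    if (any(p < 0) || any(p >= dims)) next
    out <- c(out, ijk_to_lin(p, dims))
  }
  out
}

#' Equi-volume depth metric via per-column simplex perturbation
#'
#' Implements the Bok equi-volume principle on the discrete lattice. Per
#' unit column, the voxel-count-balancing depth `m*` is the median of the
#' member equi-distant values; the equi-volume factor pair is
#' `(a, b) = (1 - m*, m*)`. The factor fields are optionally smoothed over
#' gray matter by iterations of 26-neighborhood averaging restricted to
#' code-3 voxels (averaging never crosses non-GM voxels, so kissing gyri
#' are safe), and each voxel's equi-volume metric is the simplex
#' perturbation `equivol = equidist*a / (equidist*a + (1-equidist)*b)`.
#' With zero curvature (`m* = 0.5`) this is the identity, so flat cortex
#' keeps `equivol == equidist`. Within a column the metric is strictly
#' increasing in `equidist` for `0 < a, b < 1`.
#'
#' @param metrics `layer_metrics` with `equidist` filled.
#' @param columns `unit_columns` on the same lattice.
#' @param smooth_iters iterations of 26-neighborhood factor smoothing
#'   (default 3; 0 disables).
#' @return `metrics` with `equivol` filled and per-column factors attached
#'   as attribute `factors` (data frame: `column_id`, `m_star`, `a`, `b`).
#' @export
compute_equivol <- function(metrics, columns, smooth_iters = 3) {
  stopifnot(inherits(metrics, "layer_metrics"),
            inherits(columns, "unit_columns"))
  if (is.null(metrics$equidist)) stop("equidist must be computed first")
  dims <- dim(metrics$equidist)
  ok <- which(!is.na(metrics$equidist) & !is.na(columns$column_id))
  ids <- columns$column_id[ok]
  eq <- metrics$equidist[ok]

  mstar <- tapply(eq, ids, stats::median)
  nmem <- tapply(eq, ids, length)
  mstar[nmem < 2] <- 0.5  # too few members to balance: no push, flagged
  fac <- data.frame(column_id = as.integer(names(mstar)),
                    m_star = as.numeric(mstar),
                    a = 1 - as.numeric(mstar),
                    b = as.numeric(mstar),
                    flagged = as.integer(nmem) < 2)

  a_map <- array(NA_real_, dim = dims)
  b_map <- array(NA_real_, dim = dims)
  a_map[ok] <- fac$a[match(ids, fac$column_id)]
  b_map[ok] <- fac$b[match(ids, fac$column_id)]

  if (smooth_iters > 0) {
    gm <- array(FALSE, dims); gm[ok] <- TRUE
    a_map <- smooth_gm_mean(a_map, gm, smooth_iters)
    b_map <- smooth_gm_mean(b_map, gm, smooth_iters)
  }

  x <- metrics$equidist[ok]
  av <- a_map[ok]; bv <- b_map[ok]
  denom <- x * av + (1 - x) * bv
  ev <- ifelse(denom > 0, x * av / denom, 0.5)
  equivol <- array(NA_real_, dim = dims)
  equivol[ok] <- ev
  metrics$equivol <- equivol
  attr(metrics, "factors") <- fac
  metrics
}

# iterative 26-neighborhood mean over GM voxels only (self included)
smooth_gm_mean <- function(map, gm, iters) {
  vals <- map
  vals[!gm] <- 0
  gmn <- array(as.numeric(gm), dim = dim(map))
  for (it in seq_len(iters)) {
    ssum <- vals
    scnt <- gmn
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      ssum <- ssum + shift_array_num(vals, c(dx, dy, dz))
      scnt <- scnt + shift_array_num(gmn, c(dx, dy, dz))
    }
    new <- ssum / pmax(scnt, 1)
    vals[gm] <- new[gm]
  }
  out <- map
  out[gm] <- vals[gm]
  out
}

shift_array_num <- function(a, off) {
  d <- dim(a)
  idx <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - off[k]
    i[i < 1 | i > d[k]] <- NA
    i
  })
  out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  out[is.na(out)] <- 0
  dim(out) <- d
  out
}

#' Quantize a depth metric into layer labels
#'
#' Half-open bins `[k/N, (k+1)/N)` with the last bin closed, i.e.
#' `layer_id = 1 + floor(metric * n_layers)` clamped so a metric of exactly
#' 1 lands in layer `n_layers`. Both continuous metrics remain available
#' alongside the labels.
#'
#' @param metrics `layer_metrics` with the chosen metric filled.
#' @param n_layers number of layers (>= 1).
#' @param which `"equidist"` or `"equivol"`.
#' @return `metrics` with integer array `layer_id` filled.
#' @export
quantize_layers <- function(metrics, n_layers, which = c("equidist",
                                                         "equivol")) {
  which <- match.arg(which)
  if (!is.numeric(n_layers) || n_layers < 1)
    stop("'n_layers' must be a count >= 1")
  n_layers <- as.integer(n_layers)
  m <- metrics[[which]]
  if (is.null(m)) stop("metric '", which, "' has not been computed")
  lid <- array(NA_integer_, dim = dim(m))
  ok <- !is.na(m)
  lid[ok] <- pmin(1L + as.integer(floor(m[ok] * n_layers)), n_layers)
  metrics$layer_id <- lid
  metrics
}

#' Full layering pipeline on a rim volume
#'
#' Convenience wrapper: geodesic depths, equi-distant metric, unit columns,
#' equi-volume metric, and quantized layers.
#'
#' @inheritParams grow_geodesic_depths
#' @param n_layers number of layers to quantize into.
#' @param metric which metric the `layer_id` labels quantize.
#' @param smooth_iters equi-volume factor smoothing iterations.
#' @return list with `depths` (`depth_field`), `metrics` (`layer_metrics`
#'   with both metrics and `layer_id`), and `columns` (`unit_columns`).
#' @export
layerify <- function(rim, n_layers = 3, metric = c("equivol", "equidist"),
                     smooth_iters = 3) {
  metric <- match.arg(metric)
  depths <- grow_geodesic_depths(rim)
  metrics <- compute_equidist(depths)
  columns <- build_unit_columns(rim, depths)
  metrics <- compute_equivol(metrics, columns, smooth_iters = smooth_iters)
  metrics <- quantize_layers(metrics, n_layers, which = metric)
  list(depths = depths, metrics = metrics, columns = columns)
}
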