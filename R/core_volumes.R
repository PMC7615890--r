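#' Construct a voxel grid
#'
#' The basic container for all volumes handled by the package: a 3D (or 4D,
#' for time series) numeric array plus the voxel size in mm and, for 4D
#' data, the repetition time in seconds. All algorithms operate on the voxel
#' index lattice; the NIfTI affine, when present, is carried through to
#' outputs untouched and never enters any computation.
#'
#' A volume with `dim[3] == 1` is a legal 2D image and is accepted by every
#' algorithm (lattice neighborhoods degenerate accordingly).
#'
#' @param data numeric array with 3 or 4 dimensions (2D images must be given
#'   as `c(nx, ny, 1)`).
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0;
#'   anisotropic sizes allowed).
#' @param tr repetition time in seconds (4D data only), or `NULL`.
#' @param affine optional 4x4 matrix kept for write-back.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size = c(1, 1, 1), tr = NULL,
                       affine = NULL) {
  if (is.vector(data)) stop("'data' must be a 3D or 4D array")
  nd <- length(dim(data))
  if (nd == 2L) {
    dim(data) <- c(dim(data), 1L)
    nd <- 3L
  }
  if (nd < 3L || nd > 4L)
    stop("'data' must have 3 or 4 dimensions, got ", nd)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 strictly positive values (mm)")
  if (!is.null(tr) && (!is.numeric(tr) || tr < 0))
    stop("'tr' must be a non-negative number of seconds")
  structure(list(data = data, voxel_size = voxel_size, tr = tr,
                 affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat("<voxel_grid> ", paste(d, collapse = " x "),
      " | voxel size ", paste(format(x$voxel_size), collapse = " x "),
      " mm", sep = "")
  if (!is.null(x$tr) && length(d) == 4L) cat(" | TR", x$tr, "s")
  cat("\n")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# coerce array-like input into a voxel_grid, passing voxel_grid through
as_voxel_grid <- function(x, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "voxel_grid")) return(x)
  voxel_grid(x, voxel_size = voxel_size)
}

spatial_dim <- function(grid) dim(grid$data)[1:3]

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/NIfTI-2 file (optionally gzip-compressed) into a
#' [voxel_grid]. Voxel sizes come from the header `pixdim`; for 4D images
#' the repetition time is taken from `pixdim[4]`. The affine is retained for
#' write-back but not used in any computation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [voxel_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': file not found")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read '", path, "': ", conditionMessage(e)))
  d <- dim(img)
  if (is.null(d) || length(d) < 3L || length(d) > 4L)
    stop("'", path, "' is not a 3D or 4D image (dims: ",
         paste(d, collapse = "x"), ")")
  hdr <- RNifti::niftiHeader(img)
  vs <- abs(hdr$pixdim[2:4])
  vs[vs == 0] <- 1
  tr <- if (length(d) == 4L) hdr$pixdim[5] else NULL
  voxel_grid(array(as.numeric(img), dim = d), voxel_size = vs, tr = tr,
             affine = structure(RNifti::xform(img), imagedim = NULL,
                                code = NULL))
}

#' Write a voxel grid as NIfTI
#'
#' Writes a [voxel_grid] to disk; a `.nii.gz` suffix triggers gzip
#' compression. Integer-valued data round-trip bit-exactly; float data are
#' stored at 32-bit precision unless `datatype = "double"`.
#'
#' @param grid a [voxel_grid].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI storage type: `"auto"` picks an integer type for
#'   integer-valued data and `"double"` otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = "auto") {
  grid <- as_voxel_grid(grid)
  d <- dim(grid$data)
  pd <- c(0, grid$voxel_size,
          if (length(d) == 4L && !is.null(grid$tr)) grid$tr else 0,
          0, 0, 0)
  if (datatype == "auto") {
    vals <- grid$data[is.finite(grid$data)]
    datatype <- if (length(vals) && all(vals == round(vals)) &&
                    max(abs(vals)) < 2^31) "int32" else "double"
  }
  img <- RNifti::asNifti(grid$data, reference = list(pixdim = pd))
  if (!is.null(grid$affine))
    RNifti::qform(img) <- structure(grid$affine, code = 1L)
  tryCatch(RNifti::writeNifti(img, path, datatype = datatype),
           error = function(e)
             stop("cannot write '", path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Convert an arbitrary integer segmentation into rim coding
#'
#' Relabels a segmentation volume into the four rim codes used by the
#' layering algorithms: 0 = irrelevant, 1 = inner gray matter border
#' (facing white matter), 2 = outer gray matter border (facing CSF),
#' 3 = pure gray matter. Labels absent from `mapping` map to 0.
#'
#' @param segmentation a [voxel_grid] (or array) of integer labels.
#' @param mapping named numeric vector or list, names = source labels,
#'   values in `{0,1,2,3}`; e.g. `c("10" = 1, "20" = 2, "30" = 3)`.
#' @return a [voxel_grid] whose values are rim codes.
#' @export
rimify <- function(segmentation, mapping) {
  seg <- as_voxel_grid(segmentation)
  if (length(dim(seg$data)) != 3L)
    stop("segmentation must be a single 3D volume")
  map <- unlist(mapping)
  if (is.null(names(map)) || any(names(map) == ""))
    stop("'mapping' must be fully named (source label -> rim code)")
  if (!all(map %in% 0:3))
    stop("rim codes must lie in {0, 1, 2, 3}")
  out <- array(0, dim = dim(seg$data))
  for (k in seq_along(map)) {
    lab <- suppressWarnings(as.numeric(names(map)[k]))
    if (is.na(lab)) stop("mapping name '", names(map)[k], "' is not numeric")
    out[seg$data == lab] <- map[[k]]
  }
  if (!any(out == 3))
    warning("mapping produced no code-3 (pure gray matter) voxels; ",
            "layering on this rim would be vacuous")
  voxel_grid(out, voxel_size = seg$voxel_size, affine = seg$affine)
}

#' Validate a rim volume
#'
#' Checks the rim-coding invariants and flags gray-matter voxels that could
#' not receive a depth: code-3 voxels with no 26-connected path (through
#' codes `{1,3}`) to a code-1 voxel, or no path (through `{2,3}`) to a
#' code-2 voxel.
#'
#' @param rim a rim-coded [voxel_grid].
#' @return a list with `counts` (voxels per code), `violations` (0-based
#'   voxel index matrix of flagged GM voxels), and `ok`.
#' @export
validate_rim <- function(rim) {
  rim <- as_voxel_grid(rim)
  a <- rim$data
  if (length(dim(a)) != 3L)
    stop("rim must be a single 3D anatomical volume, not a 4D series")
  bad_codes <- sum(!(a %in% 0:3))
  counts <- vapply(0:3, function(k) sum(a == k), numeric(1))
  names(counts) <- as.character(0:3)
  dims <- dim(a)
  codes <- as.integer(a)
  flagged <- integer(0)
  if (counts[["3"]] > 0) {
    gm <- which(codes == 3L)
    if (counts[["1"]] > 0) {
      g1 <- grow_geodesic_cpp(codes, dims, rim$voxel_size, 1L, c(1L, 3L))
      un1 <- gm[!is.finite(g1$dist[gm])]
    } else un1 <- gm
    if (counts[["2"]] > 0) {
      g2 <- grow_geodesic_cpp(codes, dims, rim$voxel_size, 2L, c(2L, 3L))
      un2 <- gm[!is.finite(g2$dist[gm])]
    } else un2 <- gm
    flagged <- sort(union(un1, un2))
  }
  viol <- t(vapply(flagged, function(i) lin_to_ijk(i, dims), numeric(3)))
  list(counts = counts,
       n_bad_codes = bad_codes,
       violations = viol,
       ok = bad_codes == 0 && length(flagged) == 0 && all(counts[2:4] > 0))
}

# linear (1-based) index -> 0-based (i, j, k)
lin_to_ijk <- function(i, dims) {
  i0 <- i - 1L
  c(i0 %% dims[1],
    (i0 %/% dims[1]) %% dims[2],
    i0 %/% (dims[1] * dims[2]))
}

# 0-based (i, j, k) -> linear 1-based index
ijk_to_lin <- function(ijk, dims) {
  1L + ijk[1] + dims[1] * (ijk[2] + dims[2] * ijk[3])
}
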