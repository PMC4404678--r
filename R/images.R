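#' In-memory image containers
#'
#' `ts_image()` wraps a 4D numeric array (x, y, z, time) together with its
#' voxel size, grid origin and repetition time; `vol_mask()` wraps a 3D
#' logical array on the same kind of grid. Both carry enough geometry to map
#' voxel indices to millimetre coordinates through a diagonal affine, which
#' is all the synthetic cohorts used here require.
#'
#' The origin is the mm coordinate of the centre of voxel (1,1,1). By default
#' it is chosen so that the grid is centred on (0,0,0), giving MNI-like
#' coordinates spanning both signs.
#'
#' @param data 4D numeric array (`ts_image`) or 3D array coercible to logical
#'   (`vol_mask`).
#' @param voxel_mm voxel edge lengths in mm; a scalar is recycled to 3.
#' @param origin_mm mm coordinate of the centre of voxel (1,1,1); default
#'   centres the grid on the mm origin.
#' @param tr_s repetition time in seconds (time between volumes).
#' @return An object of class `ts_image` or `vol_mask`.
#' @export
ts_image <- function(data, voxel_mm = 3, origin_mm = NULL, tr_s = 2) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, time)")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(origin_mm)) origin_mm <- -voxel_mm * (dim(data)[1:3] - 1) / 2
  structure(list(data = data, voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm), tr_s = as.numeric(tr_s)),
            class = "ts_image")
}

#' @rdname ts_image
#' @export
vol_mask <- function(data, voxel_mm = 3, origin_mm = NULL) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "logical"
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) stop("voxel sizes must be positive")
  if (is.null(origin_mm)) origin_mm <- -voxel_mm * (dim(data) - 1) / 2
  structure(list(data = data, voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "vol_mask")
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_image> %d x %d x %d voxels, %d timepoints\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %s mm, TR %.3g s\n",
              paste(format(x$voxel_mm), collapse = " x "), x$tr_s))
  invisible(x)
}

#' @export
print.vol_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol_mask> %d x %d x %d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

grid_dim <- function(x) {
  d <- dim(x$data)
  d[1:3]
}

#' Voxel-to-mm affine of an image or mask
#'
#' Returns the 4x4 affine mapping 0-based voxel indices to mm coordinates.
#' Internally all R indices are 1-based; [voxel_to_mm()] and [mm_to_voxel()]
#' take and return 1-based indices.
#'
#' @param x a `ts_image` or `vol_mask`.
#' @return 4x4 numeric matrix.
#' @export
image_affine <- function(x) {
  aff <- diag(c(x$voxel_mm, 1))
  aff[1:3, 4] <- x$origin_mm
  aff
}

#' @param ijk integer matrix (n x 3) or vector of 1-based voxel indices.
#' @rdname image_affine
#' @export
voxel_to_mm <- function(ijk, x) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, x$voxel_mm, "*"), 2L, x$origin_mm, "+")
}

#' @param mm numeric matrix (n x 3) or vector of mm coordinates.
#' @rdname image_affine
#' @export
mm_to_voxel <- function(mm, x) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  sweep(mm, 2L, x$origin_mm, "-") %*% diag(1 / x$voxel_mm) + 1
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    max(abs(a$voxel_mm - b$voxel_mm)) < tol &&
    max(abs(a$origin_mm - b$origin_mm)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("inputs are not on the same voxel grid (dimensions, voxel size and ",
         "origin must match)")
  invisible(TRUE)
}

## Extract the (timepoints x n_voxel) series matrix at the given linear
## voxel indices of the 3D grid.
series_matrix <- function(img, idx) {
  d <- dim(img$data)
  nvox <- prod(d[1:3])
  m <- matrix(img$data, nrow = nvox, ncol = d[4])
  t(m[idx, , drop = FALSE])
}

## Place a vector of per-voxel values back into a 3D array (NA elsewhere).
vec_to_vol <- function(values, idx, dim3) {
  v <- array(NA_real_, dim = dim3)
  v[idx] <- values
  v
}

#' Read and write NIfTI-1 images
#'
#' Thin wrappers around \pkg{RNifti} that preserve the voxel size, origin and
#' TR carried by [ts_image()] and [vol_mask()] objects. Masks are written as
#' 0/1 integer volumes.
#'
#' @param x a `ts_image` or `vol_mask`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_image()` returns `path` invisibly; `read_ts_image()` and
#'   `read_mask()` return the corresponding object.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "ts_image")) {
    arr <- x$data
    pix <- c(-1, x$voxel_mm, x$tr_s)
  } else if (inherits(x, "vol_mask")) {
    arr <- array(as.integer(x$data), dim = dim(x$data))
    pix <- c(-1, x$voxel_mm, 1)
  } else stop("'x' must be a ts_image or vol_mask")
  nim <- RNifti::asNifti(arr, reference = list(
    pixdim = c(1, pix[2:5], 0, 0, 0)))
  aff <- diag(c(x$voxel_mm, 1))
  aff[1:3, 4] <- x$origin_mm
  RNifti::qform(nim) <- structure(aff, code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_ts_image <- function(path) {
  nim <- RNifti::readNifti(path)
  if (length(dim(nim)) != 4L) stop("expected a 4D NIfTI at ", path)
  pd <- RNifti::pixdim(nim)
  aff <- RNifti::xform(nim)
  ts_image(array(as.numeric(nim), dim = dim(nim)), voxel_mm = pd[1:3],
           origin_mm = aff[1:3, 4], tr_s = if (length(pd) >= 4) pd[4] else 2)
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  nim <- RNifti::readNifti(path)
  if (length(dim(nim)) != 3L) stop("expected a 3D NIfTI at ", path)
  pd <- RNifti::pixdim(nim)
  aff <- RNifti::xform(nim)
  vol_mask(array(as.numeric(nim) != 0, dim = dim(nim)), voxel_mm = pd[1:3],
           origin_mm = aff[1:3, 4])
}
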