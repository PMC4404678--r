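## Small desk fixtures shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

## ROI correlation matrix: uniform `base` off-diagonals, with the first
## ROI's row/column set to `roi1` (the planted-decrease design in miniature).
conn_matrix <- function(names, base = 0.5, roi1 = base) {
  r <- length(names)
  C <- matrix(base, r, r, dimnames = list(names, names))
  C[1, -1] <- C[-1, 1] <- roi1
  diag(C) <- 1
  C
}

## A reduced cohort: 12x12x8 grid, ~500-voxel mask, three 3x3x3 ROIs.
small_spec <- function(seed = 1, n_per_group = 4, n_timepoints = 64,
                       noise_sd = 0.5, connectivity = NULL, ...) {
  ## corner blocks, mirroring the default design: mask-edge placement clips
  ## the smoothing halo of each ROI
  ## six corner blocks as in the default design (one affected, five not, so
  ## the planted decrease perturbs only a small share of each map); the
  ## corner above roiA stays empty to isolate its halo
  blk <- function(x0, y0, z0) list(bounds = rbind(lo = c(x0, y0, z0),
                                                  hi = c(x0 + 2, y0 + 2, z0 + 2)))
  rois <- list(roiA = blk(2, 2, 2),   roiB = blk(11, 2, 2),
               roiC = blk(2, 11, 2),  roiD = blk(11, 11, 2),
               roiE = blk(11, 2, 5),  roiF = blk(2, 11, 5))
  connectivity <- connectivity %||%
    list(patient = conn_matrix(names(rois), roi1 = 0.15),
         control = conn_matrix(names(rois)))
  cohort_spec(n_per_group = n_per_group, grid_shape = c(14, 14, 8),
              voxel_mm = 3, n_timepoints = n_timepoints, tr_s = 2,
              roi_defs = rois,
              mask_bounds = rbind(lo = c(2, 2, 2), hi = c(13, 13, 7)),
              connectivity = connectivity, noise_sd = noise_sd,
              link_roi = "roiA", seed = seed, ...)
}

## Two-ROI spec for targeted correlation checks.
two_roi_spec <- function(target, seed = 1, n_timepoints = 230,
                         noise_sd = 0.5) {
  rois <- list(
    roiA = list(bounds = rbind(lo = c(3, 3, 3), hi = c(5, 5, 5))),
    roiB = list(bounds = rbind(lo = c(8, 3, 3), hi = c(10, 5, 5))))
  C <- matrix(c(1, target, target, 1), 2,
              dimnames = list(names(rois), names(rois)))
  cohort_spec(n_per_group = 3, grid_shape = c(12, 12, 8), voxel_mm = 3,
              n_timepoints = n_timepoints, tr_s = 2, roi_defs = rois,
              mask_bounds = rbind(lo = c(2, 2, 2), hi = c(11, 11, 7)),
              connectivity = list(patient = C, control = C),
              noise_sd = noise_sd, link_roi = "roiA", seed = seed)
}

## Wrap a voxels x time matrix as a ts_image on an nx1x1 grid.
series_image <- function(X, tr_s = 2, voxel_mm = 3) {
  ts_image(array(X, dim = c(nrow(X), 1, 1, ncol(X))),
           voxel_mm = voxel_mm, tr_s = tr_s)
}

## All-TRUE mask matching an image or dimensions.
full_mask <- function(x) {
  d <- if (inherits(x, "ts_image")) dim(x$data)[1:3] else x
  vol_mask(array(TRUE, d), voxel_mm = if (inherits(x, "ts_image")) x$voxel_mm else 3)
}

## Box mask helper on its own grid.
box_mask <- function(dim3, voxel_mm = 3) vol_mask(array(TRUE, dim3), voxel_mm)
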