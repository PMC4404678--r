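#' Seed definition and spherical seed masks
#'
#' A seed is a named sphere in mm space (the study convention is an 8-mm
#' diameter sphere centred on a peak coordinate, i.e. a 4-mm radius — note
#' that some of the literature quotes the radius instead; here the value is
#' taken literally as a diameter). `sphere_mask()` marks every voxel whose
#' centre lies within `diameter_mm / 2` of the centre (boundary inclusive).
#'
#' @param name seed label.
#' @param center_mm length-3 mm coordinate of the sphere centre.
#' @param diameter_mm sphere diameter in mm.
#' @return `seed_spec()`: an object of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mm, diameter_mm = 8) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm), class = "seed_spec")
}

#' @rdname seed_spec
#' @param seed a `seed_spec`.
#' @param grid a [ts_image()] or [vol_mask()] supplying the voxel grid.
#' @return `sphere_mask()`: a [vol_mask()] of the sphere.
#' @export
sphere_mask <- function(seed, grid) {
  d <- grid_dim(grid)
  ijk <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  centers <- voxel_to_mm(ijk, grid)
  dist2 <- rowSums(sweep(centers, 2, seed$center_mm)^2)
  inside <- dist2 <= (seed$diameter_mm / 2)^2 + 1e-9
  if (!any(inside))
    stop("seed '", seed$name, "' produces an empty sphere: centre (",
         paste(seed$center_mm, collapse = ", "), ") mm lies outside the grid")
  m <- array(FALSE, dim = d)
  m[ijk[inside, , drop = FALSE]] <- TRUE
  vol_mask(m, voxel_mm = grid$voxel_mm, origin_mm = grid$origin_mm)
}

#' Mean seed time course
#'
#' Unweighted mean over the sphere's voxels at each timepoint.
#'
#' @param img a [ts_image()].
#' @param sphere a [vol_mask()] (typically from [sphere_mask()]).
#' @return Numeric vector of length `n_timepoints`.
#' @export
seed_timecourse <- function(img, sphere) {
  stop_if_grid_mismatch(img, sphere)
  idx <- which(sphere$data)
  if (length(idx) == 0) stop("sphere mask is empty")
  rowMeans(series_matrix(img, idx))   # series_matrix is timepoints x voxels
}

#' Seed-based resting-state functional connectivity map
#'
#' Pearson correlation of the seed's mean time course with every voxel's
#' series, Fisher z-transformed after clipping r to +/-(1 - 1e-7) so the
#' transform stays finite at self-correlation.
#'
#' @param img a [ts_image()].
#' @param seed_ts numeric seed time course (non-constant), e.g. from
#'   [seed_timecourse()].
#' @param min_variance voxels at or below this variance get `NA`.
#' @return An object of class `rsfc_map`: list with 3D arrays `r` and `z`
#'   (`NA` at degenerate voxels) and the grid geometry.
#' @export
rsfc_map <- function(img, seed_ts, min_variance = 1e-10) {
  nt <- dim(img$data)[4]
  if (length(seed_ts) != nt)
    stop("seed time course length does not match the image")
  if (stats::sd(seed_ts) == 0) stop("seed time course is constant")
  d <- dim(img$data)
  X <- t(matrix(img$data, prod(d[1:3]), d[4]))
  v <- matrixStats_colVars(X)
  s <- as.numeric(scale(seed_ts))      # centred, unit sd
  num <- as.numeric(crossprod(X, s))   # = sum (x - xbar) * s since s is centred
  r <- num / ((nt - 1) * sqrt(pmax(v, 1e-300)))
  r[v <= min_variance] <- NA
  r <- pmin(pmax(r, -1), 1)
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
  structure(list(r = array(r, d[1:3]), z = array(z, d[1:3]),
                 voxel_mm = img$voxel_mm, origin_mm = img$origin_mm),
            class = "rsfc_map")
}

#' @export
print.rsfc_map <- function(x, ...) {
  cat(sprintf("<rsfc_map> %s grid; r range [%.3f, %.3f]\n",
              paste(dim(x$r), collapse = "x"),
              min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Group-level positive connectivity network
#'
#' Random-effects one-sample t-test of the subjects' z maps against zero at
#' every voxel; voxels with positive t surviving both the voxel screen
#' (p < `p_voxel`, two-tailed) and Benjamini-Hochberg FDR at `q` form the
#' binary network mask. Voxels with zero between-subject SD (or any missing
#' value) are excluded with a warning when present.
#'
#' @param z_maps list of 3D z arrays (one per subject, same grid), e.g. the
#'   `z` component of [rsfc_map()]s.
#' @param geometry a [vol_mask()] or [ts_image()] supplying voxel geometry.
#' @param p_voxel voxel-wise two-tailed screening threshold.
#' @param q Benjamini-Hochberg false-discovery level.
#' @return A [vol_mask()] of the network.
#' @export
group_network <- function(z_maps, geometry, p_voxel = 0.001, q = 0.001) {
  n <- length(z_maps)
  if (n < 3) stop("at least 3 subjects are required for a one-sample t-test")
  d <- dim(z_maps[[1]])
  Y <- vapply(z_maps, as.numeric, numeric(prod(d)))   # voxels x subjects
  ok <- rowSums(is.na(Y)) == 0
  mu <- rowMeans(Y)
  sdv <- sqrt(pmax(rowSums((Y - mu)^2) / (n - 1), 0))
  degen <- ok & sdv == 0
  if (any(degen))
    warning(sum(degen), " voxel(s) with zero between-subject SD excluded")
  ok <- ok & sdv > 0
  if (!any(ok))
    return(vol_mask(array(FALSE, d), voxel_mm = geometry$voxel_mm,
                    origin_mm = geometry$origin_mm))
  tval <- mu[ok] / (sdv[ok] / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  rej <- fdr_threshold(p, q)
  net <- logical(prod(d))
  net[which(ok)[tval > 0 & p < p_voxel & rej]] <- TRUE
  vol_mask(array(net, d), voxel_mm = geometry$voxel_mm,
           origin_mm = geometry$origin_mm)
}

#' Union of two masks
#'
#' Voxel-wise union, used to combine the per-group connectivity networks into
#' one comparison mask.
#'
#' @param mask_a,mask_b [vol_mask()]s on the same grid.
#' @return A [vol_mask()].
#' @export
combine_masks <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a, mask_b)
  vol_mask(mask_a$data | mask_b$data, voxel_mm = mask_a$voxel_mm,
           origin_mm = mask_a$origin_mm)
}
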