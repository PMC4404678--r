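#' Voxel neighbourhood from a millimetre radius
#'
#' All nonzero integer voxel offsets whose centre-to-centre distance in mm is
#' at most `rmm`. At 3-mm isotropic voxels, the conventional `rmm = 5`
#' yields the 18-neighbourhood: faces (3.0 mm) and edges (4.243 mm) connect,
#' corners (5.196 mm) do not.
#'
#' @param rmm neighbour radius in mm (> 0).
#' @param voxel_mm voxel edge lengths in mm; scalar recycled to 3.
#' @return Integer matrix, one offset per row, columns dx, dy, dz.
#' @export
neighbor_offsets <- function(rmm, voxel_mm = 3) {
  if (rmm <= 0) stop("rmm must be positive")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  rng <- floor(rmm / voxel_mm)
  g <- as.matrix(expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                             dz = -rng[3]:rng[3]))
  dist <- sqrt(colSums((t(g) * voxel_mm)^2))
  keep <- dist <= rmm + 1e-9 & dist > 0
  g[keep, , drop = FALSE]
}

#' Connected-component labelling under an offset neighbourhood
#'
#' Labels the connected components of a binary 3D map, where two voxels are
#' connected when their index difference is one of the supplied offsets.
#'
#' @param bin logical/0-1 3D array.
#' @param offsets offset matrix from [neighbor_offsets()].
#' @return List with `labels` (integer 3D array, 0 = background) and `sizes`
#'   (voxels per cluster, in label order); both empty-cluster-free.
#' @export
label_clusters <- function(bin, offsets) {
  d <- dim(bin)
  idx <- which(bin != 0)
  lab <- array(0L, d)
  sizes <- integer(0)
  if (length(idx) == 0) return(list(labels = lab, sizes = sizes))
  noff <- nrow(offsets)
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    lab[v] <- cur
    stack <- v
    n <- 0L
    while (length(stack) > 0) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      n <- n + 1L
      uc <- arrayInd(u, d)
      nb <- offsets + matrix(uc, noff, 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(ok)) next
      nbl <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
      new <- nbl[bin[nbl] != 0 & lab[nbl] == 0L]
      if (length(new)) {
        lab[new] <- cur
        stack <- c(stack, new)
      }
    }
    sizes[cur] <- n
  }
  list(labels = lab, sizes = sizes)
}

#' Monte Carlo cluster-extent correction configuration
#'
#' Parameters of the null-field simulation that estimates the minimum cluster
#' extent controlling the family-wise error rate: voxel-level threshold,
#' assumed smoothness, mm neighbour radius, iteration count and target alpha.
#' The reference configuration is voxel p = 0.01, FWHM 6 mm, rmm = 5,
#' 1000 iterations, corrected alpha = 0.05.
#'
#' @param mask a [vol_mask()] defining the analysis region.
#' @param voxel_p voxel-level threshold probability, in (0, 1).
#' @param fwhm_mm assumed Gaussian smoothness of the maps, mm.
#' @param rmm cluster-forming neighbour radius, mm.
#' @param iterations Monte Carlo iterations (at least 100).
#' @param alpha corrected family-wise significance level.
#' @param sidedness `"two"` (default; matches two-tailed group contrasts) or
#'   `"one"`.
#' @param seed RNG seed for the simulation.
#' @return An object of class `alphasim_config`.
#' @export
alphasim_config <- function(mask, voxel_p = 0.01, fwhm_mm = 6, rmm = 5,
                            iterations = 1000, alpha = 0.05,
                            sidedness = c("two", "one"), seed = 1L) {
  sidedness <- match.arg(sidedness)
  if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must lie in (0, 1)")
  if (iterations < 100) stop("iterations must be at least 100")
  if (rmm <= 0) stop("rmm must be positive")
  if (sum(mask$data) < 2) stop("mask must contain at least 2 voxels")
  structure(list(mask = mask, voxel_p = voxel_p, fwhm_mm = fwhm_mm,
                 rmm = rmm, iterations = as.integer(iterations),
                 alpha = alpha, sidedness = sidedness, seed = as.integer(seed)),
            class = "alphasim_config")
}

## Bounding box (lo/hi index matrix) of a mask.
mask_bbox <- function(mask) {
  w <- which(mask$data, arr.ind = TRUE)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' One simulated null map on a mask
#'
#' Draws an iid standard Gaussian field on the mask bounding box, smooths it
#' at the given FWHM, standardises it voxel-wise by the exact per-voxel
#' standard deviation of the smoothed field (so every voxel has unit marginal
#' variance — reflective-boundary smoothing otherwise leaves edge voxels with
#' more than twice the interior SD, which would concentrate null exceedances
#' at mask edges, unlike the self-normalised t statistic the null stands in
#' for), restricts it to the mask, and removes the mask mean. Uses the
#' current RNG state.
#'
#' @param mask a [vol_mask()].
#' @param fwhm_mm smoothness in mm (0 = unsmoothed white noise).
#' @return Numeric vector of field values at `which(mask$data)`.
#' @export
null_field <- function(mask, fwhm_mm) {
  bb <- mask_bbox(mask)
  bd <- bb["hi", ] - bb["lo", ] + 1L
  arr <- array(rnorm(prod(bd)), dim = bd)
  if (fwhm_mm > 0) {
    sigma_vox <- fwhm_to_sigma(fwhm_mm) / mask$voxel_mm
    arr <- smooth_array3d(arr, sigma_vox)
    arr <- arr / sqrt(smooth_var_profile(bd, sigma_vox))
  }
  sub <- mask$data[bb["lo", 1]:bb["hi", 1], bb["lo", 2]:bb["hi", 2],
                   bb["lo", 3]:bb["hi", 3], drop = FALSE]
  v <- arr[sub]
  as.numeric(scale(v))
}

## Exact per-voxel variance of reflective-boundary separable smoothing of
## unit white noise: product over axes of the kernel-matrix row sums of
## squares.
smooth_var_profile <- function(bd, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  vs <- lapply(1:3, function(ax) {
    if (sigma_vox[ax] <= 0) return(rep(1, bd[ax]))
    rowSums(conv_matrix_1d(bd[ax], sigma_vox[ax])^2)
  })
  outer(outer(vs[[1]], vs[[2]]), vs[[3]])
}

## Max cluster size among supra-threshold voxels of a field on the mask,
## labelling positive and negative excursions separately (as the signed
## group contrasts are thresholded).
max_cluster_size <- function(vals, mask, thr, offsets, sidedness) {
  d <- dim(mask$data)
  idx <- which(mask$data)
  mx <- 0L
  pos <- array(FALSE, d)
  pos[idx[vals > thr]] <- TRUE
  if (any(pos)) mx <- max(mx, label_clusters(pos, offsets)$sizes)
  if (sidedness == "two") {
    neg <- array(FALSE, d)
    neg[idx[vals < -thr]] <- TRUE
    if (any(neg)) mx <- max(mx, label_clusters(neg, offsets)$sizes)
  }
  mx
}

#' Null distribution of the maximum cluster size
#'
#' The Monte Carlo engine: per iteration a smoothed, mask-restricted,
#' variance-normalised Gaussian null field is thresholded at the z quantile
#' corresponding to `voxel_p` (per sidedness) and the maximum
#' supra-threshold cluster size under the `rmm` neighbourhood is recorded.
#'
#' @param config an [alphasim_config()].
#' @return An object of class `cluster_null`: `max_sizes` (one per
#'   iteration), the threshold used, and the configuration parameters.
#' @export
simulate_null_max_sizes <- function(config) {
  set.seed(config$seed)
  thr <- if (config$sidedness == "two") qnorm(1 - config$voxel_p / 2)
         else qnorm(1 - config$voxel_p)
  offsets <- neighbor_offsets(config$rmm, config$mask$voxel_mm)
  mx <- integer(config$iterations)
  for (it in seq_len(config$iterations)) {
    vals <- null_field(config$mask, config$fwhm_mm)
    mx[it] <- max_cluster_size(vals, config$mask, thr, offsets,
                               config$sidedness)
  }
  structure(list(max_sizes = mx, threshold_z = thr,
                 voxel_p = config$voxel_p, fwhm_mm = config$fwhm_mm,
                 rmm = config$rmm, alpha = config$alpha,
                 sidedness = config$sidedness, seed = config$seed,
                 n_mask = sum(config$mask$data)),
            class = "cluster_null")
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf("<cluster_null> %d iterations (voxel p %.3g, FWHM %g mm, rmm %g, %s-sided)\n",
              length(x$max_sizes), x$voxel_p, x$fwhm_mm, x$rmm, x$sidedness))
  cat(sprintf("  max cluster size: median %g, 95th pct %g; k_crit(alpha = %.2g) = %d\n",
              stats::median(x$max_sizes),
              stats::quantile(x$max_sizes, 0.95), x$alpha,
              critical_cluster_size(x, x$alpha)))
  invisible(x)
}

#' Critical cluster size at a corrected alpha
#'
#' The smallest extent k such that the fraction of null iterations whose
#' maximum cluster reaches k is at most alpha.
#'
#' @param null_table a `cluster_null` from [simulate_null_max_sizes()], or a
#'   bare integer vector of per-iteration maxima.
#' @param alpha corrected significance level; defaults to the table's.
#' @return Integer critical size (at least 1).
#' @export
critical_cluster_size <- function(null_table, alpha = NULL) {
  mx <- if (inherits(null_table, "cluster_null")) null_table$max_sizes
        else as.numeric(null_table)
  if (length(mx) == 0) stop("empty null table")
  if (is.null(alpha)) alpha <- null_table$alpha
  for (k in seq_len(max(mx) + 1L)) {
    if (mean(mx >= k) <= alpha) {
      if (inherits(null_table, "cluster_null") && k > null_table$n_mask)
        stop("alpha is unreachable: every null iteration fills the mask")
      return(as.integer(k))
    }
  }
  stop("alpha is unreachable for this null table")
}

#' Cluster-extent thresholding of a statistic map
#'
#' Thresholds |t| at the two-tailed `voxel_p` quantile of the map's t
#' distribution, labels positive and negative supra-threshold voxels
#' separately under the `rmm` neighbourhood, and keeps clusters of at least
#' `k_crit` voxels. Peaks are reported in mm through the map's geometry.
#'
#' @param statmap a `stat_map` (with `voxel_idx` and, for mm peaks,
#'   `geometry`).
#' @param voxel_p voxel-level two-tailed threshold.
#' @param k_crit critical cluster extent, e.g. from
#'   [critical_cluster_size()].
#' @param rmm neighbour radius in mm.
#' @return An object of class `cluster_report`: data frame `clusters` (id,
#'   sign, size, peak_t, peak mm coordinates, survives), plus `survivor_mask`
#'   (a [vol_mask()] of surviving voxels) and the thresholds used.
#' @export
apply_cluster_threshold <- function(statmap, voxel_p = 0.01, k_crit = 1,
                                    rmm = 5) {
  geom <- statmap$geometry
  if (is.null(geom)) stop("statmap carries no geometry; supply one in the fit")
  d <- grid_dim(geom)
  thr <- stats::qt(1 - voxel_p / 2, df = statmap$df)
  offsets <- neighbor_offsets(rmm, geom$voxel_mm)
  rows <- list()
  surv <- array(FALSE, d)
  tv <- array(NA_real_, d)
  tv[statmap$voxel_idx] <- statmap$t
  for (sgn in c(1, -1)) {
    bin <- array(FALSE, d)
    bin[statmap$voxel_idx[sgn * statmap$t > thr]] <- TRUE
    if (!any(bin)) next
    cl <- label_clusters(bin, offsets)
    for (ci in seq_along(cl$sizes)) {
      vox <- which(cl$labels == ci)
      peak <- vox[which.max(sgn * tv[vox])]
      pk_mm <- voxel_to_mm(arrayInd(peak, d), geom)
      keep <- cl$sizes[ci] >= k_crit
      if (keep) surv[vox] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "increase" else "decrease",
        size = cl$sizes[ci], peak_t = tv[peak],
        x_mm = pk_mm[1], y_mm = pk_mm[2], z_mm = pk_mm[3], survives = keep)
    }
  }
  clusters <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(-out$size), , drop = FALSE]
    out$id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out[, c("id", "sign", "size", "peak_t", "x_mm", "y_mm", "z_mm", "survives")]
  } else data.frame(id = integer(), sign = character(), size = integer(),
                    peak_t = numeric(), x_mm = numeric(), y_mm = numeric(),
                    z_mm = numeric(), survives = logical())
  structure(list(clusters = clusters,
                 survivor_mask = vol_mask(surv, voxel_mm = geom$voxel_mm,
                                          origin_mm = geom$origin_mm),
                 voxel_p = voxel_p, k_crit = k_crit, rmm = rmm,
                 threshold_t = thr),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> voxel p < %.3g (|t| > %.2f), k_crit = %d, rmm = %g mm\n",
              x$voxel_p, x$threshold_t, x$k_crit, x$rmm))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}
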