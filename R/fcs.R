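#' Voxel-wise functional connectivity strength (weighted degree centrality)
#'
#' For every valid voxel i inside the mask, the raw FCS is
#' `k(i) = sum over valid j != i of r_ij * [r_ij > r0]`, where `r_ij` is the
#' Pearson correlation between the two voxels' time series and `r0` is the
#' connection threshold eliminating weak and negative correlations. In graph
#' terms, k is the weighted degree centrality of the voxel in the functional
#' network restricted to the mask. Voxels whose series variance does not
#' exceed `min_variance` are dropped from the valid set (they enter neither
#' the sums nor the output).
#'
#' The correlation matrix is processed in column blocks so that only a
#' `block_size x N` slab is ever held, which keeps memory flat for large
#' masks; the result is identical to dense row-sums of the thresholded
#' correlation matrix.
#'
#' @param img a preprocessed [ts_image()].
#' @param mask a [vol_mask()] on the same grid.
#' @param r0 connection threshold, in (0, 1).
#' @param min_variance variance floor below which a voxel is flagged invalid.
#' @param block_size number of voxels per correlation block.
#' @return An object of class `fcs_map`: list with `k` (raw strength, one
#'   entry per valid voxel), `voxel_idx` (their linear grid indices),
#'   `n_voxels` (mask size), `n_invalid`, `r0`, `mask`, and — after
#'   [normalize_fcs()] / [transform_fcs()] — `k0`, `k_norm`, `z` and
#'   `transform`.
#' @export
voxel_fcs <- function(img, mask, r0, min_variance = 1e-10, block_size = 1024L) {
  stop_if_grid_mismatch(img, mask)
  if (r0 <= 0 || r0 >= 1) stop("r0 must lie strictly inside (0, 1)")
  idx <- which(mask$data)
  X <- series_matrix(img, idx)
  nt <- nrow(X)
  v <- matrixStats_colVars(X)
  valid <- v > min_variance
  if (sum(valid) < 2) stop("fewer than 2 mask voxels have non-degenerate variance")
  idx_valid <- idx[valid]
  Xs <- scale(X[, valid, drop = FALSE])
  n <- ncol(Xs)
  k <- numeric(n)
  denom <- nt - 1
  start <- 1L
  while (start <= n) {
    end <- min(start + block_size - 1L, n)
    R <- crossprod(Xs[, start:end, drop = FALSE], Xs) / denom
    for (b in seq_len(end - start + 1L)) R[b, start + b - 1L] <- 0  # j != i
    k[start:end] <- rowSums(R * (R > r0))
    start <- end + 1L
  }
  structure(list(k = k, voxel_idx = idx_valid, n_voxels = length(idx),
                 n_invalid = sum(!valid), invalid_idx = idx[!valid],
                 r0 = r0, mask = mask),
            class = "fcs_map")
}

## colVars without extra dependencies.
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - colSums(X)^2 / n) / (n - 1)
}

#' Normalise an FCS map by its individual global mean
#'
#' Divides each voxel's raw strength by `k0`, the subject's mean raw FCS over
#' the valid mask voxels, so normalised maps average exactly 1 and are
#' comparable across subjects.
#'
#' @param fcs an `fcs_map` from [voxel_fcs()], or a bare numeric vector.
#' @return The input with `k0` and `k_norm` filled in (or, for a numeric
#'   input, the normalised vector with attribute `k0`).
#' @export
normalize_fcs <- function(fcs) {
  k <- if (inherits(fcs, "fcs_map")) fcs$k else as.numeric(fcs)
  k0 <- mean(k)
  if (k0 <= 0)
    stop("global mean FCS k0 is zero: no supra-threshold connections ",
         "anywhere; lower r0")
  if (inherits(fcs, "fcs_map")) {
    fcs$k0 <- k0
    fcs$k_norm <- k / k0
    fcs
  } else structure(k / k0, k0 = k0)
}

#' Transform a normalised FCS map for group comparison
#'
#' `"zscore"` standardises the map to mean 0, SD 1 over the valid voxels —
#' the usual transform in the degree-centrality literature, defined for any
#' map. `"fisher"` applies atanh literally, which is only defined when every
#' value has magnitude below 1; since normalised FCS averages 1, this mode
#' errors on typical maps and exists for the literal reading only.
#'
#' @param fcs an `fcs_map` with `k_norm` present, or a numeric vector.
#' @param mode `"zscore"` (default) or `"fisher"`.
#' @return The input with `z` and `transform` filled in (or the transformed
#'   vector).
#' @export
transform_fcs <- function(fcs, mode = c("zscore", "fisher")) {
  mode <- match.arg(mode)
  x <- if (inherits(fcs, "fcs_map")) {
    if (is.null(fcs$k_norm)) stop("call normalize_fcs() first")
    fcs$k_norm
  } else as.numeric(fcs)
  z <- if (mode == "zscore") {
    as.numeric(scale(x))
  } else {
    if (any(abs(x) >= 1))
      stop("Fisher z-transform (atanh) is undefined for |values| >= 1; ",
           "normalised FCS exceeds 1 wherever strength is above the mask ",
           "mean - use mode = \"zscore\"")
    atanh(x)
  }
  if (inherits(fcs, "fcs_map")) {
    fcs$z <- z
    fcs$transform <- mode
    fcs
  } else z
}

#' Full FCS map for one subject at one threshold
#'
#' Convenience wrapper: [voxel_fcs()], [normalize_fcs()], [transform_fcs()].
#'
#' @inheritParams voxel_fcs
#' @inheritParams transform_fcs
#' @return A complete `fcs_map`.
#' @export
fcs_map <- function(img, mask, r0 = 0.25, mode = "zscore",
                    min_variance = 1e-10) {
  transform_fcs(normalize_fcs(voxel_fcs(img, mask, r0,
                                        min_variance = min_variance)),
                mode = mode)
}

#' @rdname fcs_map
#' @param r0_values thresholds to sweep (the study convention considers
#'   0.10-0.40 in steps of 0.05, reporting 0.25 as the reference).
#' @return `fcs_sweep()`: named list of `fcs_map`s, one per threshold.
#' @export
fcs_sweep <- function(img, mask, r0_values = seq(0.10, 0.40, by = 0.05),
                      mode = "zscore", min_variance = 1e-10) {
  maps <- lapply(r0_values, function(r0)
    fcs_map(img, mask, r0, mode = mode, min_variance = min_variance))
  names(maps) <- sprintf("r0_%.2f", r0_values)
  maps
}

#' @export
print.fcs_map <- function(x, ...) {
  cat(sprintf("<fcs_map> r0 = %.2f, %d valid / %d mask voxels\n",
              x$r0, length(x$k), x$n_voxels))
  if (!is.null(x$k0))
    cat(sprintf("  k0 (global mean raw FCS) = %.4g; transform: %s\n",
                x$k0, if (is.null(x$transform)) "none" else x$transform))
  invisible(x)
}

#' Place an FCS layer back on the 3D grid
#'
#' @param fcs an `fcs_map`.
#' @param layer one of `"k"`, `"k_norm"`, `"z"`.
#' @return 3D array with `NA` outside the valid voxels.
#' @export
fcs_volume <- function(fcs, layer = c("k_norm", "k", "z")) {
  layer <- match.arg(layer)
  vals <- fcs[[layer]]
  if (is.null(vals)) stop("layer '", layer, "' not present; run normalize/transform first")
  vec_to_vol(vals, fcs$voxel_idx, dim(fcs$mask$data))
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Converts r to `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and evaluates the
#' two-tailed Student-t tail with `n - 2` degrees of freedom. At the study's
#' 230 retained volumes, the reference connection threshold r0 = 0.25
#' corresponds to p below 0.001.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param n number of timepoints (at least 4).
#' @return Two-tailed p-value(s); exactly 0 where `|r| = 1`.
#' @export
r_to_p <- function(r, n) {
  if (n < 4) stop("n must be at least 4")
  if (any(abs(r) > 1)) stop("|r| cannot exceed 1")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tval <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tval), df = n - 2)
  p
}
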