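#' Regional mean of a voxel map
#'
#' Unweighted mean of the map over the region's voxels; `NA` voxels (outside
#' the valid analysis set) are excluded.
#'
#' @param map 3D numeric array (e.g. from [fcs_volume()]) or an `fcs_map`
#'   (its `k_norm` layer is used).
#' @param region a [vol_mask()].
#' @return Scalar mean.
#' @export
region_mean <- function(map, region) {
  if (inherits(map, "fcs_map")) map <- fcs_volume(map, "k_norm")
  if (!identical(dim(map), dim(region$data)))
    stop("map and region are not on the same grid")
  idx <- which(region$data)
  if (length(idx) == 0) stop("region mask is empty")
  vals <- map[idx]
  if (all(is.na(vals))) stop("region contains no valid voxels")
  mean(vals, na.rm = TRUE)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary least
#' squares on the covariates (plus intercept) — equivalent to the t-test on
#' the regression coefficient of `x` in a model for `y` adjusted for the
#' covariates, which is how "regression controlling for age and gender"
#' reports an (r, p) pair. The p-value uses `n - 2 - k` degrees of freedom,
#' with k the number of covariate columns.
#'
#' @param x,y numeric vectors, one value per subject.
#' @param covariates data frame or matrix of covariates (factors and
#'   character columns are expanded to indicators), or `NULL` for a plain
#'   correlation.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5) stop("at least 5 subjects are required")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
  } else {
    cv <- as.data.frame(covariates, stringsAsFactors = TRUE)
    cv[] <- lapply(cv, function(col) if (is.character(col)) factor(col) else col)
    Z <- stats::model.matrix(~ ., data = cv)
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("covariate design is rank deficient")
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1))
    stop("zero residual variance: a variable is fully explained by the covariates")
  r <- stats::cor(rx, ry)
  k <- ncol(Z) - 1
  df <- n - 2 - k
  tval <- r * sqrt(df) / sqrt(max(1 - r^2, 1e-300))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = df), df = df, n = n)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` per value; `m` defaults to the number of tests supplied.
#'
#' @param p p-value(s).
#' @param m number of comparisons in the family.
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be at least 1")
  pmin(1, p * m)
}

#' Region-by-metric clinical association table
#'
#' For every (regional summary, clinical metric) pair, computes the partial
#' correlation controlling for age and sex within the given subjects and
#' applies a Bonferroni correction over the whole family of tests
#' (m = regions x metrics).
#'
#' @param summaries data frame of per-subject regional summaries (one column
#'   per region), aligned with `clinical` rows.
#' @param clinical data frame with the metric columns plus `age` and `sex`.
#' @param metrics character vector of clinical metric column names.
#' @return Data frame with columns `region`, `metric`, `r`, `p`,
#'   `p_bonferroni`, `n`, `m`.
#' @export
clinical_association <- function(summaries, clinical,
                                 metrics = c("joa", "ndi", "fa_c2")) {
  regions <- colnames(summaries)
  m <- length(regions) * length(metrics)
  rows <- list()
  for (rg in regions) for (mt in metrics) {
    pc <- partial_corr(summaries[[rg]], clinical[[mt]],
                       clinical[, c("age", "sex")])
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, metric = mt, r = pc$r, p = pc$p,
      p_bonferroni = bonferroni(pc$p, m), n = pc$n, m = m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dice overlap of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 0 when both are empty.
#'
#' @param mask_a,mask_b [vol_mask()]s (or logical arrays) on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "vol_mask")) mask_a$data else mask_a
  b <- if (inherits(mask_b, "vol_mask")) mask_b$data else mask_b
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
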