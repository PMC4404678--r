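#' Design matrix for the covariate-adjusted group comparison
#'
#' Builds the voxel-wise GLM design: intercept, group indicator (patient = 1,
#' control = 0), centred age, and a sex indicator (male = 1). With two groups
#' the ANCOVA F on the group factor and the t on this indicator are
#' equivalent (t^2 = F), so the post-hoc group t-test is read directly off
#' the GLM.
#'
#' @param clinical data frame with columns `group`, `age`, `sex` (one row per
#'   subject), e.g. from [generate_clinical()].
#' @param patient_level value of `group` coding the patient group.
#' @return Numeric matrix with columns `intercept`, `group`, `age`, `sex`.
#' @export
design_matrix <- function(clinical, patient_level = "patient") {
  X <- cbind(intercept = 1,
             group = as.numeric(clinical$group == patient_level),
             age = clinical$age - mean(clinical$age),
             sex = as.numeric(clinical$sex == "M"))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  X
}

#' Voxel-wise ordinary least squares fit
#'
#' Fits `Y = X beta + e` independently at every voxel. Voxels with a missing
#' value for any subject are dropped.
#'
#' @param maps numeric matrix, subjects x voxels, of per-subject map values
#'   (e.g. transformed FCS or seed-connectivity z values).
#' @param design design matrix, subjects x predictors, full rank, e.g. from
#'   [design_matrix()].
#' @param voxel_idx optional linear grid indices of the columns of `maps`.
#' @param geometry optional [vol_mask()]/[ts_image()] carrying the grid, used
#'   for mm peak coordinates downstream.
#' @return An object of class `voxel_glm`: betas, residual variance, df,
#'   the design, and the retained voxel indices.
#' @export
fit_voxel_glm <- function(maps, design, voxel_idx = NULL, geometry = NULL) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  if (nrow(X) != nrow(maps))
    stop("number of subjects in maps and design differ")
  keep <- colSums(is.na(maps)) == 0
  Y <- maps[, keep, drop = FALSE]
  if (is.null(voxel_idx)) voxel_idx <- seq_len(ncol(maps))
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, df = df, XtXinv = XtXinv,
                 design = X, voxel_idx = voxel_idx[keep],
                 geometry = geometry),
            class = "voxel_glm")
}

#' Group-contrast statistic map (post-hoc two-sample t)
#'
#' The t statistic of the group coefficient at every voxel, with two-tailed
#' p-values on the residual degrees of freedom. Voxels with zero residual
#' variance are assigned p = 0 and flagged with a warning.
#'
#' @param fit a `voxel_glm` from [fit_voxel_glm()].
#' @param coef name of the tested coefficient (default `"group"`).
#' @return An object of class `stat_map`: `t`, `df`, `p`, `flagged`,
#'   `voxel_idx`, `geometry`, `contrast`.
#' @export
group_contrast <- function(fit, coef = "group") {
  j <- match(coef, rownames(fit$beta))
  if (is.na(j)) stop("no coefficient named '", coef, "' in the fit")
  se <- sqrt(fit$sigma2 * fit$XtXinv[j, j])
  tval <- fit$beta[j, ] / se
  flagged <- fit$sigma2 <= 0
  if (any(flagged)) {
    warning(sum(flagged), " voxel(s) with zero residual variance; p set to 0")
    tval[flagged] <- sign(fit$beta[j, flagged]) * Inf
  }
  p <- ifelse(flagged, 0, 2 * stats::pt(-abs(tval), df = fit$df))
  structure(list(t = unname(tval), df = fit$df, p = unname(p),
                 flagged = unname(flagged), voxel_idx = fit$voxel_idx,
                 geometry = fit$geometry,
                 contrast = paste0(coef, " (patient - control)")),
            class = "stat_map")
}

#' Random-effects one-sample t-test map
#'
#' Per-voxel mean / (SD / sqrt(n)) against zero, df = n - 1; zero-SD voxels
#' are flagged (t and p set to `NA`).
#'
#' @param maps numeric matrix, subjects x voxels.
#' @param voxel_idx,geometry as in [fit_voxel_glm()].
#' @return A `stat_map`.
#' @export
one_sample_t <- function(maps, voxel_idx = NULL, geometry = NULL) {
  n <- nrow(maps)
  if (n < 3) stop("at least 3 subjects required")
  if (is.null(voxel_idx)) voxel_idx <- seq_len(ncol(maps))
  mu <- colMeans(maps)
  sdv <- sqrt(matrixStats_colVars(maps))
  flagged <- !(sdv > 0)
  tval <- ifelse(flagged, NA_real_, mu / (sdv / sqrt(n)))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  structure(list(t = tval, df = n - 1, p = p, flagged = flagged,
                 voxel_idx = voxel_idx, geometry = geometry,
                 contrast = "mean vs 0"),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- is.finite(x$t)
  cat(sprintf("<stat_map> %s; %d voxels, df = %d, t range [%.2f, %.2f]\n",
              x$contrast, length(x$t), x$df,
              min(x$t[ok]), max(x$t[ok])))
  invisible(x)
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up FDR control over the supplied p-values.
#'
#' @param p numeric vector of p-values (a `stat_map`'s `p` component).
#' @param q false-discovery level in (0, 1).
#' @return Logical rejection vector aligned with `p`.
#' @export
fdr_threshold <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value set")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  stats::p.adjust(p, method = "BH") <= q
}
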