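#' Preprocessing configuration
#'
#' Bundles the temporal/spatial conditioning parameters: number of initial
#' volumes to discard, Gaussian smoothing FWHM, band-pass edges, repetition
#' time, and the head-motion quality-control limits.
#'
#' @param discard_n initial volumes to discard (magnetic-saturation dummies).
#' @param fwhm_mm smoothing kernel full width at half maximum, mm.
#' @param band_hz band-pass edges `c(low, high)` in Hz.
#' @param tr_s repetition time in seconds; `NULL` to take it from the image.
#' @param motion_disp_limit_mm maximum allowed translation (strict), mm.
#' @param motion_rot_limit_deg maximum allowed rotation (strict), degrees.
#' @param stage_order order in which the three conditioning stages run.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(discard_n = 0, fwhm_mm = 6,
                           band_hz = c(0.01, 0.08), tr_s = NULL,
                           motion_disp_limit_mm = 2.0,
                           motion_rot_limit_deg = 2.0,
                           stage_order = c("smooth", "bandpass", "regress")) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (!(band_hz[1] >= 0 && band_hz[1] < band_hz[2]))
    stop("band_hz must satisfy 0 <= low < high")
  stage_order <- match.arg(stage_order, c("smooth", "bandpass", "regress"),
                           several.ok = TRUE)
  structure(list(discard_n = as.integer(discard_n), fwhm_mm = fwhm_mm,
                 band_hz = band_hz, tr_s = tr_s,
                 motion_disp_limit_mm = motion_disp_limit_mm,
                 motion_rot_limit_deg = motion_rot_limit_deg,
                 stage_order = stage_order),
            class = "preproc_config")
}

#' Head-motion quality control
#'
#' A subject fails if any translation exceeds the displacement limit or any
#' rotation exceeds the rotation limit, read as strict inequalities, so
#' maxima exactly at the limit pass.
#'
#' @param motion matrix or data frame with six columns: three translations
#'   (mm) then three rotations (degrees); series of equal length.
#' @param disp_limit_mm translation limit, mm (default 2).
#' @param rot_limit_deg rotation limit, degrees (default 2).
#' @return An object of class `motion_qc`: list with `pass`, per-axis
#'   `max_translation_mm` and `max_rotation_deg`.
#' @export
motion_qc <- function(motion, disp_limit_mm = 2.0, rot_limit_deg = 2.0) {
  if (is.data.frame(motion) || is.list(motion)) {
    lens <- lengths(motion)
    if (length(unique(lens)) != 1) stop("motion series have unequal lengths")
    motion <- do.call(cbind, as.list(motion))
  }
  if (ncol(motion) != 6) stop("motion must have six columns (3 translations, 3 rotations)")
  mx <- apply(abs(motion), 2, max)
  out <- list(pass = !(any(mx[1:3] > disp_limit_mm) || any(mx[4:6] > rot_limit_deg)),
              max_translation_mm = mx[1:3], max_rotation_deg = mx[4:6],
              disp_limit_mm = disp_limit_mm, rot_limit_deg = rot_limit_deg)
  class(out) <- "motion_qc"
  out
}

#' @export
print.motion_qc <- function(x, ...) {
  cat(sprintf("<motion_qc> %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max translation (mm): %s (limit > %g fails)\n",
              paste(format(x$max_translation_mm, digits = 3), collapse = " "),
              x$disp_limit_mm))
  cat(sprintf("  max rotation (deg):   %s (limit > %g fails)\n",
              paste(format(x$max_rotation_deg, digits = 3), collapse = " "),
              x$rot_limit_deg))
  invisible(x)
}

## FWHM (mm) to Gaussian sigma (mm).
fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

## 1D convolution matrix with symmetric (reflective) boundary handling;
## preserves constants because the kernel sums to one and every tap is
## folded back inside the support.
conv_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  R <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-R):R)^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  reflect <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  for (i in seq_len(n))
    for (d in (-R):R) {
      j <- reflect(i + d)
      K[i, j] <- K[i, j] + w[d + R + 1]
    }
  K
}

smooth_array3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  d4 <- if (length(d) == 3L) c(d, 1L) else d
  a <- array(arr, dim = d4)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- conv_matrix_1d(d4[ax], sigma_vox[ax])
    perm <- c(ax, setdiff(1:4, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(K %*% matrix(ap, nrow = dp[1]), dim = dp)
    a <- aperm(ap, order(perm))
  }
  array(a, dim = d)
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable 3D Gaussian kernel of the given
#' FWHM (sigma = FWHM / (2 * sqrt(2 * log 2)) per axis, in mm, honouring
#' anisotropic voxel sizes), with reflective boundary handling so constant
#' volumes are unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param img a [ts_image()].
#' @param fwhm_mm kernel FWHM in mm; scalar or per-axis length 3.
#' @return The smoothed `ts_image`.
#' @export
smooth_spatial <- function(img, fwhm_mm) {
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be non-negative")
  if (all(fwhm_mm == 0)) return(img)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / img$voxel_mm
  img$data <- smooth_array3d(img$data, sigma_vox)
  img
}

## R (1-based) indices of the DFT bins whose frequencies lie in [low, high],
## positive frequencies plus their conjugate mirrors.
band_bin_index <- function(nt, tr_s, low, high) {
  k <- 1:floor(nt / 2)           # positive-frequency bin numbers
  f <- k / (nt * tr_s)
  keep <- k[f >= low - 1e-12 & f <= high + 1e-12]
  unique(c(keep + 1L, nt - keep + 1L))   # conjugate mirrors; Nyquist self-pairs
}

## Project the columns of X (timepoints x series) onto the span of the
## retained DFT bins.
band_project <- function(X, bins) {
  nt <- nrow(X)
  Fx <- stats::mvfft(X)
  keepmask <- rep(FALSE, nt)
  keepmask[bins] <- TRUE
  Fx[!keepmask, ] <- 0
  Re(stats::mvfft(Fx, inverse = TRUE)) / nt
}

#' Temporal band-pass filter
#'
#' Ideal (DFT bin selection) band-pass: per-voxel discrete Fourier transform,
#' retention of the bins whose frequencies lie inside the band, and inverse
#' transform; all other bins, including the zero-frequency (mean) bin, are
#' zeroed. On top of the bin selection the band-limited component of a linear
#' trend is removed, making the whole operation the exact orthogonal
#' projection onto (in-band span) intersected with the trend complement —
#' the output is band-limited, mean- and trend-free, and the filter is
#' idempotent to machine precision.
#'
#' @param img a [ts_image()], or a numeric matrix (timepoints x series).
#' @param band_hz band edges `c(low, high)` in Hz.
#' @param tr_s repetition time in seconds; defaults to the image's.
#' @return Object of the same type as `img`, filtered.
#' @export
bandpass <- function(img, band_hz = c(0.01, 0.08), tr_s = NULL) {
  is_img <- inherits(img, "ts_image")
  if (is_img && is.null(tr_s)) tr_s <- img$tr_s
  if (is.null(tr_s)) stop("tr_s must be supplied for matrix input")
  X <- if (is_img) {
    d <- dim(img$data)
    t(matrix(img$data, prod(d[1:3]), d[4]))
  } else as.matrix(img)
  nt <- nrow(X)
  if (nt < 8) stop("time series must have at least 8 points")
  nyq <- 1 / (2 * tr_s)
  if (band_hz[2] > nyq + 1e-12)
    stop(sprintf("band upper edge %.4g Hz exceeds the Nyquist frequency %.4g Hz",
                 band_hz[2], nyq))
  bins <- band_bin_index(nt, tr_s, band_hz[1], band_hz[2])
  if (length(bins) == 0) stop("no DFT bins fall inside the requested band")
  Y <- band_project(X, bins)
  tb <- band_project(matrix(seq_len(nt) - (nt + 1) / 2, ncol = 1), bins)
  nb2 <- sum(tb^2)
  if (nb2 > 1e-12) Y <- Y - tb %*% (crossprod(tb, Y) / nb2)
  if (is_img) {
    img$data <- array(t(Y), dim = dim(img$data))
    img
  } else Y
}

#' Nuisance regression
#'
#' Regresses an intercept, the white-matter and CSF mean series, and the six
#' head-motion parameters out of every voxel's time series; the returned
#' residuals are orthogonal to every regressor.
#'
#' @param img a [ts_image()].
#' @param nuisance data frame or matrix with columns `wm`, `csf`, `tx_mm`,
#'   `ty_mm`, `tz_mm`, `rx_deg`, `ry_deg`, `rz_deg` (or any eight nuisance
#'   series), one row per retained timepoint.
#' @return The residual `ts_image`.
#' @export
regress_nuisance <- function(img, nuisance) {
  N <- as.matrix(nuisance)
  d <- dim(img$data)
  if (nrow(N) != d[4])
    stop("nuisance series length (", nrow(N),
         ") does not match the number of timepoints (", d[4], ")")
  X <- cbind(intercept = 1, N)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("nuisance design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  Y <- t(matrix(img$data, prod(d[1:3]), d[4]))
  res <- qr.resid(qx, Y)
  img$data <- array(t(res), dim = d)
  img
}

#' Run the full preprocessing chain on one subject
#'
#' Applies, in the configured order: initial volume discard, spatial
#' smoothing, temporal band-pass filtering, and nuisance regression. Each
#' stage is a linear operator on the retained series.
#'
#' @param img a [ts_image()].
#' @param nuisance nuisance series table (see [regress_nuisance()]); rows for
#'   discarded volumes are dropped together with the volumes.
#' @param config a [preproc_config()].
#' @return The preprocessed `ts_image`.
#' @export
preprocess_subject <- function(img, nuisance, config = preproc_config()) {
  tr <- if (is.null(config$tr_s)) img$tr_s else config$tr_s
  if (config$discard_n > 0) {
    d <- dim(img$data)
    keep <- (config$discard_n + 1):d[4]
    img$data <- img$data[, , , keep, drop = FALSE]
    nuisance <- nuisance[keep, , drop = FALSE]
  }
  for (stage in config$stage_order) {
    img <- switch(stage,
      smooth = smooth_spatial(img, config$fwhm_mm),
      bandpass = bandpass(img, config$band_hz, tr),
      regress = regress_nuisance(img, nuisance))
  }
  img
}
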