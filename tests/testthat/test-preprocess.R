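test_that("motion QC applies strict thresholds per axis", {
  mk <- function(tmax, rmax) cbind(matrix(0.1, 20, 2), c(rep(0, 19), tmax),
                                   matrix(0.1, 20, 2), c(rep(0, 19), rmax))
  expect_false(motion_qc(mk(2.1, 0.5))$pass)     # > 2 mm fails
  expect_false(motion_qc(mk(0.5, 2.3))$pass)     # > 2 deg fails
  expect_true(motion_qc(mk(1.9, 1.9))$pass)
  expect_true(motion_qc(mk(2.0, 2.0))$pass)      # boundary passes (strict >)
  qc <- motion_qc(mk(1.5, 0.7))
  expect_equal(unname(qc$max_translation_mm[3]), 1.5)
  expect_equal(unname(qc$max_rotation_deg[3]), 0.7)
  expect_error(motion_qc(list(1:3, 1:2, 1:3, 1:3, 1:3, 1:3)), "unequal")
})

test_that("Gaussian smoothing uses sigma = FWHM / 2.3548 and conserves mass", {
  d <- c(15, 15, 15)
  arr <- array(0, c(d, 1))
  arr[8, 8, 8, 1] <- 1
  img <- ts_image(arr, voxel_mm = 3)
  sm <- smooth_spatial(img, 6)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)   # kernel normalisation
  ## profile ratio pins the mm sigma of the discrete kernel
  sigma_mm <- sqrt(-9 / (2 * log(sm$data[9, 8, 8, 1] / sm$data[8, 8, 8, 1])))
  expect_equal(sigma_mm, 6 / (2 * sqrt(2 * log(2))), tolerance = 1e-8)
  expect_equal(sigma_mm, 2.548, tolerance = 1e-3)

  const <- ts_image(array(3.7, c(8, 8, 8, 2)), voxel_mm = 3)
  expect_equal(smooth_spatial(const, 6)$data, const$data, tolerance = 1e-12)
  expect_identical(smooth_spatial(const, 0)$data, const$data)
  expect_error(smooth_spatial(const, -1), "non-negative")
})

test_that("band-pass keeps in-band sinusoids, kills out-of-band and DC", {
  nt <- 256; tr <- 2
  t_s <- (0:(nt - 1)) * tr
  inband <- sin(2 * pi * 0.05 * t_s)
  outband <- sin(2 * pi * (100 / (nt * tr)) * t_s)   # 0.195 Hz, bin-aligned
  X <- cbind(inband, outband, rep(4, nt))
  Y <- bandpass(X, c(0.01, 0.08), tr)
  expect_gte(sum(Y[, 1]^2) / sum(X[, 1]^2), 0.99)
  expect_lt(max(abs(Y[, 2])), 1e-8)
  expect_lt(max(abs(Y[, 3])), 1e-12)
  expect_error(bandpass(X, c(0.01, 0.3), tr), "Nyquist")
})

test_that("band-pass is an orthogonal projection: idempotent and trend-free", {
  set.seed(1)
  X <- matrix(rnorm(230 * 5), 230, 5) + outer(1:230, runif(5), "*")
  Y1 <- bandpass(X, c(0.01, 0.08), 2)
  Y2 <- bandpass(Y1, c(0.01, 0.08), 2)
  expect_lt(max(abs(Y2 - Y1)), 1e-10)
  tt <- 1:230 - mean(1:230)
  expect_lt(max(abs(crossprod(tt, Y1))) / 230, 1e-8)
  expect_lt(max(abs(colSums(Y1))), 1e-8)
})

test_that("nuisance regression returns residuals orthogonal to the design", {
  set.seed(2)
  nt <- 60
  nuis <- data.frame(wm = rnorm(nt), csf = rnorm(nt),
                     tx_mm = rnorm(nt), ty_mm = rnorm(nt), tz_mm = rnorm(nt),
                     rx_deg = rnorm(nt), ry_deg = rnorm(nt), rz_deg = rnorm(nt))
  X <- cbind(nuis$wm, rnorm(nt), rnorm(nt))
  img <- series_image(t(X))
  res <- regress_nuisance(img, nuis)
  ## a voxel equal to the wm series is fully absorbed
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-10)
  ## residuals orthogonal to every regressor
  R <- t(matrix(res$data, 3, nt))
  expect_lt(max(abs(crossprod(as.matrix(nuis), R))), 1e-8)
  expect_lt(max(abs(colSums(R))), 1e-8)

  ## a series orthogonal to all regressors only loses its mean
  Q <- qr.Q(qr(cbind(1, as.matrix(nuis))))
  v <- rnorm(nt)
  v_orth <- v - Q %*% crossprod(Q, v)
  v_test <- v_orth + 5
  img2 <- series_image(matrix(v_test, 1))
  res2 <- regress_nuisance(img2, nuis)
  expect_equal(as.numeric(res2$data[1, 1, 1, ]),
               as.numeric(v_test - mean(v_test)), tolerance = 1e-8)

  ## rank deficiency is reported with the offending column
  bad <- nuis
  bad$csf <- bad$wm
  expect_error(regress_nuisance(img, bad), "collinear")
})

test_that("the preprocessing chain is linear in its input", {
  spec <- small_spec(seed = 13, n_timepoints = 48)
  co <- generate_cohort(spec)
  a <- subject_image(co, 1)
  b <- subject_image(co, 2)
  nuis <- attr(a, "nuisance")
  cfg <- preproc_config(tr_s = 2)
  ab <- a
  ab$data <- a$data + b$data
  out_sum <- preprocess_subject(ab, nuis, cfg)
  out_a <- preprocess_subject(a, nuis, cfg)
  b2 <- b
  out_b <- preprocess_subject(b2, nuis, cfg)
  expect_equal(out_sum$data, out_a$data + out_b$data, tolerance = 1e-8)
})

test_that("initial volume discard drops volumes and nuisance rows together", {
  spec <- small_spec(seed = 14, n_timepoints = 40)
  co <- generate_cohort(spec)
  img <- subject_image(co, 1)
  cfg <- preproc_config(discard_n = 8, fwhm_mm = 0, tr_s = 2)
  out <- preprocess_subject(img, attr(img, "nuisance"), cfg)
  expect_equal(dim(out$data)[4], 32)
})
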