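make_clin <- function(n_per_group = 10, seed = 1) {
  set.seed(seed)
  data.frame(group = rep(c("patient", "control"), each = n_per_group),
             age = rnorm(2 * n_per_group, 50, 6),
             sex = sample(rep(c("M", "F"), c(n_per_group + 2,
                                             n_per_group - 2))))
}

test_that("voxel GLM matches lm() at a single voxel", {
  clin <- make_clin(8)
  X <- design_matrix(clin)
  set.seed(2)
  y <- rnorm(16) + 0.8 * X[, "group"]
  fit <- fit_voxel_glm(matrix(y, ncol = 1), X)
  ref <- lm(y ~ 0 + X)
  expect_equal(unname(fit$beta[, 1]), unname(coef(ref)), tolerance = 1e-10)
  cm <- group_contrast(fit)
  ref_t <- summary(ref)$coefficients["Xgroup", ]
  expect_equal(cm$t, unname(ref_t["t value"]), tolerance = 1e-10)
  expect_equal(cm$p, unname(ref_t["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(cm$df, 12L)   # 16 subjects - 4 columns
})

test_that("degenerate and shifted inputs behave linearly", {
  clin <- make_clin(6)
  X <- design_matrix(clin)
  zero_fit <- fit_voxel_glm(matrix(0, 12, 5), X)
  expect_true(all(zero_fit$beta == 0))
  expect_true(all(zero_fit$sigma2 == 0))
  expect_warning(cm <- group_contrast(zero_fit), "zero residual")
  expect_true(all(cm$p == 0))

  set.seed(3)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  f1 <- fit_voxel_glm(Y, X)
  f2 <- fit_voxel_glm(Y + 5, X)
  expect_equal(f2$beta["intercept", ], f1$beta["intercept", ] + 5,
               tolerance = 1e-10)
  expect_equal(f2$beta["group", ], f1$beta["group", ], tolerance = 1e-10)

  Xbad <- cbind(X, dup = X[, "group"])
  expect_error(fit_voxel_glm(Y, Xbad), "rank deficient")
})

test_that("with no covariates the GLM group t equals the pooled two-sample t", {
  set.seed(4)
  n <- 14
  g <- rep(c(1, 0), each = n / 2)
  y <- rnorm(n) + 0.5 * g
  fit <- fit_voxel_glm(matrix(y, ncol = 1), cbind(intercept = 1, group = g))
  cm <- group_contrast(fit)
  ref <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  expect_equal(cm$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cm$p, ref$p.value, tolerance = 1e-10)
})

test_that("covariates orthogonal to group and outcome leave the contrast as a mean difference", {
  clin <- make_clin(10, seed = 5)
  set.seed(6)
  y <- rnorm(20) + 0.4 * (clin$group == "patient")
  X <- design_matrix(clin)
  ## orthogonalise age and sex against intercept, group and the outcome
  base <- cbind(1, X[, "group"], y)
  for (cc in c("age", "sex")) X[, cc] <- qr.resid(qr(base), X[, cc])
  fit <- fit_voxel_glm(matrix(y, ncol = 1), X)
  cm <- group_contrast(fit)
  md <- mean(y[clin$group == "patient"]) - mean(y[clin$group == "control"])
  expect_equal(unname(fit$beta["group", 1]), md, tolerance = 1e-10)
  ## same RSS and coefficient, so t differs only by the residual-df ratio
  ref <- t.test(y[clin$group == "patient"], y[clin$group == "control"],
                var.equal = TRUE)
  expect_equal(cm$t, unname(ref$statistic) * sqrt((20 - 4) / (20 - 2)),
               tolerance = 1e-10)
})

test_that("one-sample t matches its closed form and is sign-equivariant", {
  set.seed(7)
  n <- 31
  x <- as.numeric(scale(rnorm(n))) * 0.1 + 0.3   # exact mean 0.3, sd 0.1
  sm <- one_sample_t(matrix(x, ncol = 1))
  expect_equal(sm$t, 0.3 / (0.1 / sqrt(n)), tolerance = 1e-10)
  expect_equal(sm$t, 16.71, tolerance = 1e-3)
  expect_equal(sm$df, n - 1)
  neg <- one_sample_t(matrix(-x, ncol = 1))
  expect_equal(neg$t, -sm$t, tolerance = 1e-12)
  zero <- one_sample_t(matrix(0, 5, 2))
  expect_true(all(zero$flagged))
  expect_true(all(is.na(zero$t)))
})

test_that("Benjamini-Hochberg step-up matches the worked example", {
  expect_equal(sum(fdr_threshold(c(0.001, 0.02, 0.04, 0.9), 0.05)), 2L)
  expect_equal(sum(fdr_threshold(rep(1, 10), 0.05)), 0L)
  expect_equal(sum(fdr_threshold(rep(0, 10), 0.05)), 10L)
  expect_error(fdr_threshold(numeric(0), 0.05), "empty")
  ## agreement with p.adjust as independent reference
  set.seed(8)
  p <- runif(50)^2
  expect_identical(fdr_threshold(p, 0.1), p.adjust(p, "BH") <= 0.1)
})

test_that("null cohorts give the nominal voxel-wise type-I rate", {
  mask <- box_mask(c(10, 10, 10))
  out <- voxelwise_type1(mask, n_per_group = 15, n_replicates = 10,
                         p_threshold = 0.01, seed = 9)
  se <- sqrt(0.01 * 0.99 / out$n_tests)
  expect_lt(abs(out$rate - 0.01), 4 * se + 1e-4)
})
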