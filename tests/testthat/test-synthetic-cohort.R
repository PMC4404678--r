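test_that("the generator is a pure function of spec and seed", {
  spec <- small_spec(seed = 11, n_timepoints = 32)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(subject_image(co1, 2)$data, subject_image(co2, 2)$data)
  co3 <- generate_cohort(small_spec(seed = 12, n_timepoints = 32))
  expect_false(identical(subject_image(co1, 2)$data,
                         subject_image(co3, 2)$data))
})

test_that("planted cross-ROI correlations are realised in the voxel data", {
  ## perfectly shared latent signal, no noise -> unit cross-ROI correlation
  spec1 <- two_roi_spec(target = 1.0, noise_sd = 0, n_timepoints = 64)
  spec1$subject_conn_sd <- 0   # the target itself, not a subject-scaled one
  co <- generate_cohort(spec1)
  img <- subject_image(co, 1)
  a <- img$data[4, 4, 4, ]
  b <- img$data[9, 4, 4, ]
  expect_equal(cor(a, b), 1.0, tolerance = 1e-10)

  ## target 0.6 within Pearson sampling error at T = 230
  spec2 <- two_roi_spec(target = 0.6, noise_sd = 0, seed = 3)
  spec2$subject_conn_sd <- 0   # isolate the target from subject scaling
  co2 <- generate_cohort(spec2)
  img2 <- subject_image(co2, 1)
  r <- cor(img2$data[4, 4, 4, ], img2$data[9, 4, 4, ])
  expect_lt(abs(r - 0.6), 0.1)
})

test_that("a non-PSD group matrix errors naming the offending eigenvalue", {
  nm <- names(small_spec()$roi_defs)
  C <- conn_matrix(nm, base = 0)
  C[1, 2] <- C[2, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- 0.9   # 0.9-0.9 chain: min eigenvalue 1 - 0.9*sqrt(2)
  spec <- small_spec(connectivity = list(patient = C, control = C))
  spec$subject_conn_sd <- 0
  co <- generate_cohort(spec)
  expect_error(subject_image(co, 1), "eigenvalue")
})

test_that("clinical table matches the emulated cohort design", {
  spec <- small_spec(seed = 5, n_per_group = 31)
  co <- generate_cohort(spec)
  clin <- co$clinical
  pat <- clin[clin$group == "patient", ]
  ctl <- clin[clin$group == "control", ]
  expect_true(all(ctl$joa == 17))             # control ceiling
  expect_equal(sum(pat$sex == "M"), 22)       # fixed male/female split
  expect_equal(sum(ctl$sex == "M"), 22)
  expect_equal(sum(pat$neck_pain), 12)
  expect_equal(sum(pat$multilevel), 20)
  expect_true(all(pat$joa <= 17 & pat$joa >= 0))
  expect_true(all(clin$fa_c2 > 0 & clin$fa_c2 < 1))
  ## moments across a larger draw
  big <- small_spec(seed = 6, n_per_group = 400)
  clin_b <- generate_cohort(big)$clinical
  pat_b <- clin_b[clin_b$group == "patient", ]
  expect_lt(abs(mean(pat_b$age) - 51.38), 1)
  expect_lt(abs(mean(pat_b$joa) - 11.45), 0.5)
  expect_lt(abs(sd(pat_b$joa) - 2.45), 0.5)
  expect_error(generate_cohort(small_spec(n_per_group = 2)), "at least 3")
})

test_that("the clinical link is exact at zero noise and absent at zero link", {
  ## link = 1, moderate mean so no clamping: deterministic linear map
  spec <- small_spec(seed = 2, n_per_group = 20)
  spec$clinical_model$patient$joa <- c(mean = 8, sd = 1, link = 1)
  set.seed(1)
  clin <- generate_clinical(spec)
  pat <- clin[clin$group == "patient", ]
  expect_equal(cor(pat$planted_strength, pat$joa), 1.0, tolerance = 1e-12)

  ## link = 0: |r| should rarely exceed the n = 31 critical value
  spec0 <- small_spec(seed = 3, n_per_group = 31)
  spec0$clinical_model$patient$joa <- c(mean = 11.45, sd = 2.45, link = 0)
  hits <- 0L
  set.seed(99)
  for (i in 1:40) {
    clin <- generate_clinical(spec0)
    pat <- clin[clin$group == "patient", ]
    if (abs(cor(pat$planted_strength, pat$joa)) < 0.355) hits <- hits + 1L
  }
  expect_gte(hits, 33L)
})

test_that("within-ROI coherence falls as voxel noise rises", {
  within_cor <- function(noise_sd) {
    spec <- small_spec(seed = 7, noise_sd = noise_sd, n_timepoints = 96)
    img <- subject_image(generate_cohort(spec), 1)
    vox <- rbind(c(3, 3, 3), c(4, 4, 4), c(5, 5, 5), c(3, 5, 4))
    X <- sapply(seq_len(nrow(vox)), function(i)
      img$data[vox[i, 1], vox[i, 2], vox[i, 3], ])
    R <- cor(X)
    mean(R[upper.tri(R)])
  }
  r <- vapply(c(0.3, 0.8, 1.5), within_cor, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("realised latent correlations converge to the target", {
  spec <- small_spec(seed = 9, n_timepoints = 2000)
  spec$subject_conn_sd <- 0
  co <- generate_cohort(spec)
  img <- subject_image(co, 1)
  L <- attr(img, "latent_cor")
  target <- spec$connectivity$patient
  expect_lt(mean(abs(L - target)[upper.tri(L)]), 0.05)
})

test_that("write_cohort emits a complete, reproducible, seed-tracking set", {
  spec <- small_spec(seed = 4, n_per_group = 3, n_timepoints = 24)
  co <- generate_cohort(spec)
  d1 <- withr::local_tempdir()
  man1 <- write_cohort(co, d1, overwrite = TRUE)
  ## 6 subjects x (image + nuisance) + mask + clinical + ground truth
  expect_length(man1$files, 15L)
  expect_error(write_cohort(co, d1), "overwrite")

  img_mem <- subject_image(co, 1)
  img_disk <- read_ts_image(file.path(d1, paste0(co$clinical$subject[1],
                                                 "_bold.nii.gz")))
  expect_equal(img_disk$data, img_mem$data, tolerance = 1e-6)
  expect_equal(img_disk$voxel_mm, img_mem$voxel_mm)

  ## same seed -> same checksums; new seed -> image checksums change
  d2 <- withr::local_tempdir()
  man2 <- write_cohort(co, d2, overwrite = TRUE)
  expect_identical(unname(unlist(man1$files)), unname(unlist(man2$files)))
  spec3 <- small_spec(seed = 5, n_per_group = 3, n_timepoints = 24)
  d3 <- withr::local_tempdir()
  man3 <- write_cohort(generate_cohort(spec3), d3, overwrite = TRUE)
  expect_false(identical(unname(unlist(man1$files))[1],
                         unname(unlist(man3$files))[1]))
})
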