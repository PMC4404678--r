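#' Specification of a synthetic two-group resting-state cohort
#'
#' Describes a desk-scale stand-in for a patient/control resting-state fMRI
#' study: a voxel grid, a sensory-motor-network-like analysis mask containing
#' labelled ROI blocks, per-group ROI-by-ROI target correlation matrices, a
#' noise model, nuisance-signal amplitudes, and a clinical model linking each
#' subject's planted connectivity to myelopathy scores.
#'
#' Each subject receives a connectivity scale factor `f ~ N(1, subject_conn_sd)`
#' multiplying the off-diagonal entries of their group's ROI correlation
#' matrix, so that between-subject variation in connectivity exists and can be
#' linked to clinical scores. Clinical scores are linear in the subject's
#' planted normalised connectivity strength plus Gaussian noise; the link is
#' parameterised by a target correlation so that downstream recovery of the
#' association is testable.
#'
#' The default layout plants a group difference in the first ROI ("roi1"):
#' in the patient group its correlations with every other ROI are reduced
#' below the reference connection threshold, producing a focal decrease in
#' functional connectivity strength with known location.
#'
#' @param n_per_group subjects per group (patient and control).
#' @param grid_shape voxel grid dimensions (x, y, z).
#' @param voxel_mm voxel edge length in mm (isotropic).
#' @param n_timepoints retained BOLD volumes per subject.
#' @param tr_s repetition time, seconds.
#' @param roi_defs named list of ROIs, each a list with element `bounds`, a
#'   2x3 matrix of inclusive voxel index ranges; `NULL` for the default
#'   corner-block layout.
#' @param mask_bounds 2x3 matrix of inclusive voxel ranges of the box-shaped
#'   analysis mask; `NULL` for the default.
#' @param connectivity named list with per-group ROI correlation matrices
#'   (`patient`, `control`); `NULL` for the default planted-decrease design.
#' @param noise_sd standard deviation of iid voxel noise added to the unit-sd
#'   ROI latent signals.
#' @param spatial_fwhm_mm FWHM of optional spatial smoothing applied to the
#'   generated noise field (0 = none; intrinsic smoothness is normally left to
#'   the pipeline's own smoothing stage).
#' @param subject_conn_sd SD of the per-subject connectivity scale factor.
#' @param nuisance_model amplitudes of the global white-matter/CSF confound
#'   series and the motion-coupled component, plus the motion random-walk step
#'   sizes (mm and degrees per volume).
#' @param clinical_model per-score `c(mean, sd, link)` triples for the patient
#'   group, where `link` is the target correlation between the score and the
#'   planted regional connectivity strength, plus control-group moments.
#' @param link_roi name of the ROI whose planted normalised strength drives
#'   the clinical scores.
#' @param r0_ref reference connection threshold used when computing planted
#'   expected strengths.
#' @param seed integer RNG seed from which all cohort randomness derives.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 31,
                        grid_shape = c(24, 24, 18),
                        voxel_mm = 3,
                        n_timepoints = 230,
                        tr_s = 2,
                        roi_defs = NULL,
                        mask_bounds = NULL,
                        connectivity = NULL,
                        noise_sd = 0.5,
                        spatial_fwhm_mm = 0,
                        subject_conn_sd = 0.12,
                        nuisance_model = list(wm = 0.4, csf = 0.4,
                                              motion_coupling = 0.1,
                                              motion_step_mm = 0.02,
                                              motion_step_deg = 0.02),
                        clinical_model = NULL,
                        link_roi = "roi1",
                        r0_ref = 0.25,
                        seed = 1L) {
  if (n_timepoints < 10) stop("n_timepoints must be at least 10")
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask_bounds))
    mask_bounds <- rbind(lo = c(6, 6, 6), hi = c(19, 19, 13))
  if (is.null(roi_defs)) roi_defs <- default_roi_layout()
  if (is.null(connectivity))
    connectivity <- default_connectivity(names(roi_defs))
  if (is.null(clinical_model)) clinical_model <- default_clinical_model()
  spec <- structure(list(
    n_per_group = as.integer(n_per_group), grid_shape = grid_shape,
    voxel_mm = voxel_mm, n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
    roi_defs = roi_defs, mask_bounds = mask_bounds,
    connectivity = connectivity, noise_sd = noise_sd,
    spatial_fwhm_mm = spatial_fwhm_mm, subject_conn_sd = subject_conn_sd,
    nuisance_model = nuisance_model, clinical_model = clinical_model,
    link_roi = link_roi, r0_ref = r0_ref, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

## Six 4x4x4 ROI blocks in the corners of the default 14x14x8 mask box.
## Corner placement clips the smoothing halo of each block at the mask edge,
## and roi1's vertically adjacent corner is left empty so the planted focal
## decrease stays spatially isolated.
default_roi_layout <- function() {
  blk <- function(x0, y0, z0) list(bounds = rbind(lo = c(x0, y0, z0),
                                                  hi = c(x0 + 3, y0 + 3, z0 + 3)))
  list(roi1 = blk(6, 6, 6),   roi2 = blk(16, 6, 6),
       roi3 = blk(6, 16, 6),  roi4 = blk(16, 16, 6),
       roi5 = blk(16, 6, 10), roi6 = blk(6, 16, 10))
}

## Patients: roi1 decoupled (0.15, below the reference threshold after
## attenuation); controls: uniform 0.5 between all ROI pairs.
default_connectivity <- function(roi_names) {
  r <- length(roi_names)
  ctrl <- matrix(0.5, r, r, dimnames = list(roi_names, roi_names))
  diag(ctrl) <- 1
  pat <- ctrl
  pat[1, -1] <- pat[-1, 1] <- 0.15
  list(patient = pat, control = ctrl)
}

## Patient-group score moments follow the study cohort this generator
## emulates (JOA 11.45 +/- 2.45, NDI 0.316 +/- 0.114, FA at C2
## 0.613 +/- 0.050, FA at the most stenotic level 0.511 +/- 0.078); `link`
## is the target correlation with planted regional connectivity strength.
default_clinical_model <- function() {
  list(patient = list(joa = c(mean = 11.45, sd = 2.45, link = 0.6),
                      ndi = c(mean = 0.316, sd = 0.114, link = -0.3),
                      fa_c2 = c(mean = 0.613, sd = 0.050, link = 0.35),
                      fa_severe = c(mean = 0.511, sd = 0.078, link = 0)),
       control = list(joa = c(mean = 17, sd = 0, link = 0),
                      ndi = c(mean = 0.011, sd = 0.001, link = 0),
                      fa_c2 = c(mean = 0.673, sd = 0.052, link = 0),
                      fa_severe = c(mean = 0.662, sd = 0.045, link = 0)),
       age = list(patient = c(mean = 51.38, sd = 6.33),
                  control = c(mean = 50.91, sd = 6.31)),
       males_per_group = 22 / 31,
       neck_pain_prev = 12 / 31,
       multilevel_prev = 20 / 31)
}

validate_cohort_spec <- function(spec) {
  for (grp in names(spec$connectivity)) {
    C <- spec$connectivity[[grp]]
    if (!isSymmetric(unname(C)) || any(abs(diag(C) - 1) > 1e-12))
      stop("group connectivity matrix for '", grp,
           "' must be symmetric with unit diagonal")
    if (any(C < -1 | C > 1)) stop("connectivity entries must lie in [-1, 1]")
  }
  if (!spec$link_roi %in% names(spec$roi_defs))
    stop("link_roi '", spec$link_roi, "' is not among the ROI names (",
         paste(names(spec$roi_defs), collapse = ", "), ")")
  idx <- lapply(spec$roi_defs, roi_voxel_idx, spec = spec)
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx)) stop("roi_defs must be disjoint voxel sets")
  mask <- cohort_mask(spec)
  if (!all(mask$data[all_idx])) stop("all ROI voxels must lie inside the mask")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d + %d subjects, %s grid at %g mm, %d volumes (TR %g s)\n",
              x$n_per_group, x$n_per_group,
              paste(x$grid_shape, collapse = "x"), x$voxel_mm,
              x$n_timepoints, x$tr_s))
  cat(sprintf("  mask %d voxels, %d ROI blocks; noise_sd %g; seed %d\n",
              sum(cohort_mask(x)$data), length(x$roi_defs), x$noise_sd, x$seed))
  invisible(x)
}

## Linear (3D) voxel indices of an ROI's block.
roi_voxel_idx <- function(roi, spec) {
  b <- roi$bounds
  d <- spec$grid_shape
  if (any(b["lo", ] < 1) || any(b["hi", ] > d))
    stop("ROI bounds fall outside the grid")
  ijk <- as.matrix(expand.grid(x = b["lo", 1]:b["hi", 1],
                               y = b["lo", 2]:b["hi", 2],
                               z = b["lo", 3]:b["hi", 3]))
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] - 1) + d[1] * d[2] * (ijk[, 3] - 1))
}

#' Analysis mask and ROI labels of a synthetic cohort
#'
#' `cohort_mask()` returns the box-shaped analysis mask of the spec as a
#' [vol_mask()]; `roi_label_volume()` returns an integer array labelling each
#' ROI block (0 = outside all ROIs).
#'
#' @param spec a [cohort_spec()].
#' @return A `vol_mask`, or an integer 3D array.
#' @export
cohort_mask <- function(spec) {
  d <- spec$grid_shape
  m <- array(FALSE, dim = d)
  b <- spec$mask_bounds
  m[b["lo", 1]:b["hi", 1], b["lo", 2]:b["hi", 2], b["lo", 3]:b["hi", 3]] <- TRUE
  vol_mask(m, voxel_mm = spec$voxel_mm)
}

#' @rdname cohort_mask
#' @export
roi_label_volume <- function(spec) {
  lab <- array(0L, dim = spec$grid_shape)
  for (i in seq_along(spec$roi_defs))
    lab[roi_voxel_idx(spec$roi_defs[[i]], spec)] <- i
  lab
}

## Per-subject ROI correlation matrix: off-diagonals scaled by the subject
## factor f, clipped to keep the matrix positive semi-definite.
subject_connectivity <- function(spec, group, f) {
  C <- spec$connectivity[[group]]
  Cs <- diag(nrow(C)) + f * (C - diag(nrow(C)))
  dimnames(Cs) <- dimnames(C)
  Cs
}

## Expected voxel-level correlation implied by a latent ROI correlation c:
## both voxels carry unit-sd latent signal plus independent noise.
attenuation <- function(noise_sd) 1 / (1 + noise_sd^2)

## Planted (idealised, pre-smoothing) FCS of each ROI under a subject or
## group ROI matrix: supra-threshold expected voxel correlations summed over
## partners, normalised by the mask mean.
planted_fcs <- function(spec, C) {
  a <- attenuation(spec$noise_sd)
  sizes <- vapply(spec$roi_defs, function(r)
    prod(r$bounds["hi", ] - r$bounds["lo", ] + 1), numeric(1))
  r0 <- spec$r0_ref
  k <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    within <- if (a > r0) (sizes[i] - 1) * a else 0
    cross <- 0
    for (j in seq_along(sizes)) if (j != i) {
      cij <- C[i, j] * a
      if (cij > r0) cross <- cross + sizes[j] * cij
    }
    k[i] <- within + cross
  }
  n_mask <- sum(cohort_mask(spec)$data)
  k0 <- sum(k * sizes) / n_mask   # background voxels contribute ~0
  names(k) <- names(spec$roi_defs)
  list(k = k, k_norm = k / k0, k0 = k0)
}

#' Generate the clinical covariate table of a synthetic cohort
#'
#' Draws ages and assigns sexes to match the emulated cohort's moments (a
#' fixed male/female split per group), gives every control the ceiling JOA
#' score of 17, and generates patient JOA/NDI/FA scores as linear functions of
#' each subject's planted normalised connectivity strength plus noise, so
#' that the downstream association analysis has a known recoverable signal.
#' Symptom indicator columns (neck/shoulder pain; multi-level compression) are
#' planted at the emulated prevalences as exact counts.
#'
#' Randomness is drawn from the current RNG state; [generate_cohort()] seeds
#' it from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` with one row per subject: `subject`, `group`
#'   (`"patient"`/`"control"`), `age`, `sex`, `joa`, `ndi`, `fa_c2`,
#'   `fa_severe`, `neck_pain`, `multilevel`, and the generator-internal
#'   columns `conn_factor` (subject connectivity scale) and `planted_strength`
#'   (planted normalised FCS of the linked ROI).
#' @export
generate_clinical <- function(spec) {
  if (spec$n_per_group < 3)
    stop("n_per_group must be at least 3 (correlations downstream are ",
         "undefined for smaller groups)")
  cm <- spec$clinical_model
  n <- spec$n_per_group
  rows <- list()
  for (grp in c("patient", "control")) {
    f <- rnorm(n, 1, spec$subject_conn_sd)
    f <- pmin(pmax(f, 0.4), 1.4)
    strength <- vapply(f, function(fi)
      planted_fcs(spec, subject_connectivity(spec, grp, fi))$k_norm[spec$link_roi],
      numeric(1))
    zs <- if (stats::sd(strength) > 0) as.numeric(scale(strength)) else rep(0, n)
    age <- rnorm(n, cm$age[[grp]]["mean"], cm$age[[grp]]["sd"])
    n_male <- round(cm$males_per_group * n)
    sex <- sample(rep(c("M", "F"), c(n_male, n - n_male)))
    score <- function(par) {
      link <- par[["link"]]
      par[["mean"]] + par[["sd"]] * (link * zs +
        sqrt(max(0, 1 - link^2)) * rnorm(n))
    }
    joa <- pmin(pmax(score(cm[[grp]]$joa), 0), 17)
    ndi <- pmin(pmax(score(cm[[grp]]$ndi), 0), 1)
    fa_c2 <- pmin(pmax(score(cm[[grp]]$fa_c2), 0.01), 0.99)
    fa_sv <- pmin(pmax(score(cm[[grp]]$fa_severe), 0.01), 0.99)
    if (grp == "patient") {
      pain <- sample(rep(c(TRUE, FALSE),
                         c(round(cm$neck_pain_prev * n),
                           n - round(cm$neck_pain_prev * n))))
      multi <- sample(rep(c(TRUE, FALSE),
                          c(round(cm$multilevel_prev * n),
                            n - round(cm$multilevel_prev * n))))
    } else pain <- multi <- rep(FALSE, n)
    rows[[grp]] <- data.frame(
      subject = sprintf("%s%02d", if (grp == "patient") "csm" else "hsc",
                        seq_len(n)),
      group = grp, age = age, sex = sex, joa = joa, ndi = ndi,
      fa_c2 = fa_c2, fa_severe = fa_sv, neck_pain = pain, multilevel = multi,
      conn_factor = f, planted_strength = as.numeric(strength),
      stringsAsFactors = FALSE)
  }
  out <- rbind(rows$patient, rows$control)
  rownames(out) <- NULL
  out
}

#' Generate one subject's 4D BOLD time-series image
#'
#' Each ROI's voxels share a latent band-limited (0.01-0.08 Hz) unit-variance
#' signal; cross-ROI latent correlations are imposed by mixing independent
#' band-limited series through the symmetric square root of the subject's ROI
#' correlation matrix. Independent Gaussian voxel noise is added everywhere,
#' and two global confound series (white-matter- and CSF-like) plus a
#' motion-coupled component are added with the spec's amplitudes. The true
#' nuisance series are attached as `attr(, "nuisance")` (a data frame with
#' columns `wm`, `csf`, `tx_mm`, `ty_mm`, `tz_mm`, `rx_deg`, `ry_deg`,
#' `rz_deg`), and the realised latent ROI correlation matrix as
#' `attr(, "latent_cor")`.
#'
#' @param spec a [cohort_spec()].
#' @param subject one row of the table from [generate_clinical()] (list or
#'   single-row data frame with `group` and `conn_factor`).
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return A [ts_image()] with attributes `nuisance` and `latent_cor`.
#' @export
generate_subject_timeseries <- function(spec, subject, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  grp <- as.character(subject$group)
  if (!grp %in% names(spec$connectivity))
    stop("subject group '", grp, "' not present in the connectivity model")
  f <- as.numeric(subject$conn_factor)
  C <- subject_connectivity(spec, grp, f)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf("subject ROI correlation matrix is not positive semi-definite (eigenvalue %.6g)",
                 min(ev$values)))
  nt <- spec$n_timepoints
  nroi <- nrow(C)
  d <- spec$grid_shape
  nvox <- prod(d)

  ## band-limited latent signals, mixed to the target correlation
  bins <- band_bin_index(nt, spec$tr_s, 0.01, 0.08)
  L <- matrix(rnorm(nt * nroi), nt, nroi)
  L <- band_project(L, bins)
  L <- scale(L)   # unit sd so the square-root mixing sets correlations
  M <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  S <- L %*% M

  ## voxel data: noise everywhere, latent signal on ROI blocks
  dat <- matrix(rnorm(nvox * nt, sd = sqrt(1 + spec$noise_sd^2)), nvox, nt)
  for (i in seq_len(nroi)) {
    idx <- roi_voxel_idx(spec$roi_defs[[i]], spec)
    dat[idx, ] <- matrix(rnorm(length(idx) * nt, sd = spec$noise_sd),
                         length(idx), nt) +
      matrix(S[, i], nrow = length(idx), ncol = nt, byrow = TRUE)
  }

  ## nuisance: global confounds plus slow motion random walks
  nm <- spec$nuisance_model
  wm <- as.numeric(scale(band_project(matrix(rnorm(nt)), bins)))
  csf <- as.numeric(scale(band_project(matrix(rnorm(nt)), bins)))
  motion <- sapply(seq_len(6), function(k)
    cumsum(rnorm(nt, 0, if (k <= 3) nm$motion_step_mm else nm$motion_step_deg)))
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  global <- nm$wm * wm + nm$csf * csf +
    nm$motion_coupling * rowSums(scale(motion, scale = FALSE))
  dat <- dat + matrix(global, nrow = nvox, ncol = nt, byrow = TRUE)

  arr <- array(dat, dim = c(d, nt))
  if (spec$spatial_fwhm_mm > 0) {
    img0 <- ts_image(arr, voxel_mm = spec$voxel_mm, tr_s = spec$tr_s)
    arr <- smooth_spatial(img0, spec$spatial_fwhm_mm)$data
  }
  img <- ts_image(arr, voxel_mm = spec$voxel_mm, tr_s = spec$tr_s)
  attr(img, "nuisance") <- data.frame(wm = wm, csf = csf, motion)
  attr(img, "latent_cor") <- stats::cor(S)
  img
}

## Deterministic per-subject seed stream.
subject_seed <- function(spec, i) (spec$seed %% 1000000L) * 1000L + i

#' Generate a synthetic cohort (clinical table, mask, ground truth)
#'
#' Seeds the RNG from `spec$seed`, draws the clinical table, and assembles
#' the ground-truth record: each subject's connectivity scale factor and ROI
#' correlation matrix target, the planted per-ROI expected normalised FCS for
#' both groups (and its ranking), and the clinical link settings. Subject
#' images are not held in memory; `subject_image(cohort, i)` regenerates
#' subject `i`'s 4D image reproducibly from the spec.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `clinical`, `mask`, and `truth`.
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  clinical <- generate_clinical(spec)
  pf <- lapply(c(patient = "patient", control = "control"), function(g)
    planted_fcs(spec, spec$connectivity[[g]]))
  truth <- list(
    conn_factor = stats::setNames(clinical$conn_factor, clinical$subject),
    planted_strength = stats::setNames(clinical$planted_strength,
                                       clinical$subject),
    expected_k_norm = lapply(pf, `[[`, "k_norm"),
    fcs_ranking = lapply(pf, function(p) names(sort(p$k_norm, decreasing = TRUE))),
    decreased_rois = names(which(pf$patient$k_norm < pf$control$k_norm - 1e-9)),
    link_roi = spec$link_roi,
    clinical_model = spec$clinical_model)
  structure(list(spec = spec, clinical = clinical, mask = cohort_mask(spec),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @rdname generate_cohort
#' @param cohort a `synthetic_cohort`.
#' @param i subject index (row of `cohort$clinical`).
#' @export
subject_image <- function(cohort, i) {
  generate_subject_timeseries(cohort$spec, cohort$clinical[i, ],
                              seed = subject_seed(cohort$spec, i))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  planted decreased-FCS ROI(s): %s\n",
              paste(x$truth$decreased_rois, collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one 4D NIfTI per subject, the analysis mask NIfTI, one nuisance TSV
#' per subject, the clinical covariate TSV, the ground-truth JSON, and a
#' manifest JSON listing every file with its MD5 checksum.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param out_dir output directory (created if absent).
#' @param overwrite overwrite an existing non-empty directory?
#' @return The manifest, invisibly: a list with `files` (named MD5 checksums)
#'   and `seed`.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir,
         " exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (i in seq_len(nrow(cohort$clinical))) {
    id <- cohort$clinical$subject[i]
    img <- subject_image(cohort, i)
    p_img <- file.path(out_dir, paste0(id, "_bold.nii.gz"))
    write_image(img, p_img)
    p_nui <- file.path(out_dir, paste0(id, "_nuisance.tsv"))
    utils::write.table(attr(img, "nuisance"), p_nui, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p_img, p_nui)
  }
  p_mask <- file.path(out_dir, "mask.nii.gz")
  write_image(cohort$mask, p_mask)
  p_clin <- file.path(out_dir, "clinical.tsv")
  utils::write.table(cohort$clinical, p_clin, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_truth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(cohort$truth, p_truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p_mask, p_clin, p_truth)
  manifest <- list(seed = cohort$spec$seed,
                   files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
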