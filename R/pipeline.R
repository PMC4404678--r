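#' Run the full functional-connectivity-strength study on a synthetic cohort
#'
#' End-to-end orchestration: cohort generation, per-subject preprocessing
#' (smoothing, band-pass, nuisance regression) with motion QC, FCS mapping at
#' the reference connection threshold with global-mean normalisation and
#' map-wise standardisation, covariate-adjusted voxel-wise group contrast,
#' Monte Carlo cluster-extent correction, per-cluster regional FCS summaries,
#' and partial-correlation association with the clinical metrics in the
#' patient group.
#'
#' Subjects are processed one at a time, so only one 4D image is ever in
#' memory.
#'
#' @param spec a [cohort_spec()]; its `seed` drives all randomness.
#' @param r0 connection threshold for the FCS maps.
#' @param preproc a [preproc_config()]; `NULL` for the defaults with the
#'   spec's TR.
#' @param voxel_p voxel-level threshold of the group comparison.
#' @param alpha corrected cluster-level significance.
#' @param alphasim_iters Monte Carlo iterations for the critical size.
#' @param rmm cluster-forming neighbour radius, mm.
#' @param metrics clinical metric columns tested against regional FCS.
#' @param out_dir optional directory: when given, tables, statistic images
#'   and a checksum manifest are written there.
#' @param verbose print stage progress.
#' @return An object of class `fcs_study`: the cohort (clinical table, ground
#'   truth, mask), per-subject QC, the normalised FCS matrix (`k_norm`,
#'   subjects x mask voxels) and its standardised version, the group
#'   `stat_map`, the `cluster_null` table, `k_crit`, the `cluster_report`,
#'   per-subject regional summaries and the association table.
#' @export
run_fcs_study <- function(spec = cohort_spec(), r0 = 0.25, preproc = NULL,
                          voxel_p = 0.01, alpha = 0.05,
                          alphasim_iters = 1000, rmm = 5,
                          metrics = c("joa", "ndi", "fa_c2"),
                          out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cohort <- generate_cohort(spec)
  mask <- cohort$mask
  if (is.null(preproc)) preproc <- preproc_config(tr_s = spec$tr_s)
  n_sub <- nrow(cohort$clinical)
  mask_idx <- which(mask$data)
  k_norm <- matrix(NA_real_, n_sub, length(mask_idx))
  z_maps <- matrix(NA_real_, n_sub, length(mask_idx))
  qc <- vector("list", n_sub)
  say("preprocessing and FCS mapping for %d subjects", n_sub)
  for (i in seq_len(n_sub)) {
    img <- subject_image(cohort, i)
    nuis <- attr(img, "nuisance")
    qc[[i]] <- motion_qc(nuis[, 3:8],
                         preproc$motion_disp_limit_mm,
                         preproc$motion_rot_limit_deg)
    img <- preprocess_subject(img, nuis, preproc)
    fm <- fcs_map(img, mask, r0 = r0, mode = "zscore")
    pos <- match(fm$voxel_idx, mask_idx)
    k_norm[i, pos] <- fm$k_norm
    z_maps[i, pos] <- fm$z
  }
  names(qc) <- cohort$clinical$subject

  say("group contrast (ANCOVA GLM, age and sex adjusted)")
  X <- design_matrix(cohort$clinical)
  fit <- fit_voxel_glm(z_maps, X, voxel_idx = mask_idx, geometry = mask)
  contrast <- group_contrast(fit)

  say("Monte Carlo cluster-extent correction (%d iterations)", alphasim_iters)
  cfg <- alphasim_config(mask, voxel_p = voxel_p,
                         fwhm_mm = preproc$fwhm_mm, rmm = rmm,
                         iterations = alphasim_iters, alpha = alpha,
                         seed = spec$seed + 1L)
  null_table <- simulate_null_max_sizes(cfg)
  k_crit <- critical_cluster_size(null_table, alpha)
  report <- apply_cluster_threshold(contrast, voxel_p = voxel_p,
                                    k_crit = k_crit, rmm = rmm)

  surv <- report$clusters[report$clusters$survives, , drop = FALSE]
  say("%d surviving cluster(s); summarising and associating", nrow(surv))
  summaries <- NULL
  assoc <- NULL
  if (nrow(surv) > 0) {
    lab_masks <- cluster_masks(report, mask)
    summaries <- vapply(lab_masks, function(cm) {
      idx <- which(cm$data[mask_idx])
      rowMeans(k_norm[, idx, drop = FALSE], na.rm = TRUE)
    }, numeric(n_sub))
    colnames(summaries) <- names(lab_masks)
    pat <- cohort$clinical$group == "patient"
    assoc <- clinical_association(as.data.frame(summaries[pat, , drop = FALSE]),
                                  cohort$clinical[pat, ], metrics = metrics)
  }
  study <- structure(list(
    spec = spec, clinical = cohort$clinical, truth = cohort$truth,
    mask = mask, mask_idx = mask_idx, qc = qc, r0 = r0,
    k_norm = k_norm, z_maps = z_maps, stat_map = contrast,
    null_table = null_table, k_crit = k_crit, report = report,
    summaries = summaries, associations = assoc,
    preproc = preproc, voxel_p = voxel_p, alpha = alpha, rmm = rmm),
    class = "fcs_study")
  if (!is.null(out_dir)) study$manifest <- write_study(study, out_dir)
  study
}

## Binary masks of the surviving clusters of a cluster_report.
cluster_masks <- function(report, geometry) {
  surv <- report$clusters[report$clusters$survives, , drop = FALSE]
  d <- dim(report$survivor_mask$data)
  out <- list()
  if (nrow(surv) == 0) return(out)
  ## relabel the survivor mask so each cluster gets its own mask
  offs <- neighbor_offsets(report$rmm, geometry$voxel_mm)
  lab <- label_clusters(report$survivor_mask$data, offs)
  for (ci in seq_along(lab$sizes)) {
    m <- array(lab$labels == ci, d)
    out[[sprintf("cluster_%02d", ci)]] <-
      vol_mask(m, voxel_mm = geometry$voxel_mm, origin_mm = geometry$origin_mm)
  }
  out
}

#' @export
print.fcs_study <- function(x, ...) {
  cat(sprintf("<fcs_study> %d + %d subjects, r0 = %.2f, mask %d voxels\n",
              sum(x$clinical$group == "patient"),
              sum(x$clinical$group == "control"),
              x$r0, length(x$mask_idx)))
  cat(sprintf("  voxel p < %.3g, corrected alpha %.2g -> k_crit = %d voxels\n",
              x$voxel_p, x$alpha, x$k_crit))
  surv <- x$report$clusters[x$report$clusters$survives, , drop = FALSE]
  cat(sprintf("  surviving clusters: %d (%s)\n", nrow(surv),
              if (nrow(surv)) paste(sprintf("%s %d vox", surv$sign, surv$size),
                                    collapse = "; ") else "none"))
  invisible(x)
}

#' @export
summary.fcs_study <- function(object, ...) {
  print(object)
  cat("\nClusters:\n")
  print(object$report$clusters, row.names = FALSE)
  if (!is.null(object$associations)) {
    cat("\nClinical associations (patient group, age/sex adjusted):\n")
    print(object$associations, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Seed-based network follow-up of an FCS study
#'
#' Places one spherical seed at the peak of each surviving FCS cluster (or at
#' user-supplied seeds), extracts per-subject seed maps from freshly
#' preprocessed images, builds each group's positive one-sample network
#' (voxel p and FDR q), combines the two group networks into a comparison
#' mask, runs the covariate-adjusted group contrast with Monte Carlo
#' cluster-extent correction inside that mask, and associates the mean
#' connectivity of each surviving cluster with the clinical metrics.
#'
#' With no surviving FCS clusters and no seed override, the function returns
#' an empty-result object (`status = "empty"`) rather than failing.
#'
#' @param study an `fcs_study` from [run_fcs_study()].
#' @param seeds optional list of [seed_spec()]s overriding peak placement.
#' @param seed_diameter_mm sphere diameter for auto-placed seeds.
#' @param network_p,network_q voxel screen and FDR level of the one-sample
#'   group networks.
#' @param metrics clinical metric columns for the edge associations.
#' @param verbose print stage progress.
#' @return An object of class `seed_study`: per-seed group networks, combined
#'   masks, contrast stat maps, cluster reports, per-subject edge summaries
#'   and association tables.
#' @export
run_seed_study <- function(study, seeds = NULL, seed_diameter_mm = 8,
                           network_p = 0.001, network_q = 0.001,
                           metrics = c("joa", "ndi", "fa_c2"),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- study$spec
  mask <- study$mask
  if (is.null(seeds)) {
    surv <- study$report$clusters[study$report$clusters$survives, ,
                                  drop = FALSE]
    if (nrow(surv) == 0)
      return(structure(list(status = "empty", seeds = list(),
                            message = "no surviving FCS clusters to seed from"),
                       class = "seed_study"))
    seeds <- lapply(seq_len(nrow(surv)), function(i)
      seed_spec(sprintf("peak_%s_%02d", surv$sign[i], surv$id[i]),
                c(surv$x_mm[i], surv$y_mm[i], surv$z_mm[i]),
                seed_diameter_mm))
  }
  cohort <- list(spec = spec, clinical = study$clinical, mask = mask)
  class(cohort) <- "synthetic_cohort"
  n_sub <- nrow(study$clinical)
  d <- grid_dim(mask)
  say("seed maps for %d seeds x %d subjects", length(seeds), n_sub)
  z_by_seed <- lapply(seeds, function(s)
    matrix(NA_real_, n_sub, prod(d)))
  names(z_by_seed) <- vapply(seeds, `[[`, "", "name")
  spheres <- lapply(seeds, sphere_mask, grid = mask)
  for (i in seq_len(n_sub)) {
    img <- subject_image(cohort, i)
    img <- preprocess_subject(img, attr(img, "nuisance"), study$preproc)
    for (si in seq_along(seeds)) {
      ts <- seed_timecourse(img, spheres[[si]])
      z_by_seed[[si]][i, ] <- as.numeric(rsfc_map(img, ts)$z)
    }
  }
  pat <- study$clinical$group == "patient"
  X <- design_matrix(study$clinical)
  out_seeds <- list()
  for (si in seq_along(seeds)) {
    nm <- names(z_by_seed)[si]
    say("seed %s: group networks and contrast", nm)
    zmat <- z_by_seed[[si]]
    to_arrays <- function(rows) lapply(which(rows), function(i)
      array(zmat[i, ], d))
    net_pat <- group_network(to_arrays(pat), mask, network_p, network_q)
    net_ctl <- group_network(to_arrays(!pat), mask, network_p, network_q)
    comb <- combine_masks(net_pat, net_ctl)
    res <- list(seed = seeds[[si]], network_patient = net_pat,
                network_control = net_ctl, combined_mask = comb)
    if (sum(comb$data) >= 2) {
      idx <- which(comb$data)
      fit <- fit_voxel_glm(zmat[, idx, drop = FALSE], X,
                           voxel_idx = idx, geometry = mask)
      contrast <- group_contrast(fit)
      cfg <- alphasim_config(comb, voxel_p = study$voxel_p,
                             fwhm_mm = study$preproc$fwhm_mm,
                             rmm = study$rmm,
                             iterations = length(study$null_table$max_sizes),
                             alpha = study$alpha, seed = spec$seed + 100L + si)
      k_crit <- critical_cluster_size(simulate_null_max_sizes(cfg),
                                      study$alpha)
      rep_si <- apply_cluster_threshold(contrast, study$voxel_p, k_crit,
                                        study$rmm)
      res$stat_map <- contrast
      res$k_crit <- k_crit
      res$report <- rep_si
      cms <- cluster_masks(rep_si, mask)
      if (length(cms)) {
        edges <- vapply(cms, function(cm)
          rowMeans(zmat[, which(cm$data), drop = FALSE]), numeric(n_sub))
        colnames(edges) <- paste0(nm, "_", names(cms))
        res$edge_summaries <- edges
        res$associations <- clinical_association(
          as.data.frame(edges[pat, , drop = FALSE]),
          study$clinical[pat, ], metrics = metrics)
      }
    }
    out_seeds[[nm]] <- res
  }
  structure(list(status = "ok", seeds = out_seeds,
                 network_p = network_p, network_q = network_q),
            class = "seed_study")
}

#' @export
print.seed_study <- function(x, ...) {
  if (x$status == "empty") {
    cat("<seed_study> empty result:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<seed_study> %d seed(s)\n", length(x$seeds)))
  for (nm in names(x$seeds)) {
    s <- x$seeds[[nm]]
    nsurv <- if (!is.null(s$report))
      sum(s$report$clusters$survives) else 0L
    cat(sprintf("  %s: networks %d/%d voxels (patient/control), combined %d, %d surviving contrast cluster(s)\n",
                nm, sum(s$network_patient$data), sum(s$network_control$data),
                sum(s$combined_mask$data), nsurv))
  }
  invisible(x)
}

## Write study outputs and a checksum manifest.
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, w(study$clinical, "clinical.tsv"),
             w(study$report$clusters, "clusters.tsv"))
  if (!is.null(study$associations))
    paths <- c(paths, w(study$associations, "associations.tsv"))
  nt <- data.frame(iteration = seq_along(study$null_table$max_sizes),
                   max_size = study$null_table$max_sizes)
  paths <- c(paths, w(nt, "cluster_null.tsv"))
  d <- grid_dim(study$mask)
  tvol <- vec_to_vol(study$stat_map$t, study$stat_map$voxel_idx, d)
  tvol[is.na(tvol)] <- 0
  nim <- RNifti::asNifti(tvol)
  p_t <- file.path(out_dir, "group_t.nii.gz")
  RNifti::writeNifti(nim, p_t)
  paths <- c(paths, p_t)
  manifest <- list(k_crit = study$k_crit, seed = study$spec$seed,
                   files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
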