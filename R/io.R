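nifti_affine <- function(img) {
  aff <- try(structure(RNifti::xform(img), imagedim = NULL, code = NULL),
             silent = TRUE)
  if (inherits(aff, "try-error") || !is.matrix(aff)) diag(4)
  else matrix(as.numeric(aff), 4, 4)
}

#' Read a 4D BOLD NIfTI file
#'
#' The repetition time comes from `tr_s` when given (configuration wins over
#' headers, which are often unreliable); otherwise from the header's fourth
#' pixdim.  A >1% mismatch between the two logs a warning.
#'
#' @param path Path to a NIfTI-1 file with 4D data.
#' @param tr_s Optional repetition-time override (seconds).
#' @return A [bold_series()].
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    abort(sprintf("'%s' is %dD; a BOLD series must be 4D.", path, length(dim(img))))
  hdr_tr <- RNifti::pixdim(img)[4]
  tr <- tr_s %||% hdr_tr
  if (!is.null(tr_s) && is.finite(hdr_tr) && hdr_tr > 0 &&
      abs(tr_s - hdr_tr) > 0.01 * hdr_tr)
    warn(sprintf("Configured TR %.4g s differs from header TR %.4g s in '%s'.",
                 tr_s, hdr_tr, basename(path)))
  if (!is.finite(tr) || tr <= 0)
    abort(sprintf("No usable TR for '%s': header gives %.4g and no override supplied.",
                  path, hdr_tr))
  bold_series(array(as.numeric(img), dim(img)), tr_s = tr,
              affine = nifti_affine(img))
}

#' Write a BOLD series as float32 NIfTI
#' @param series A [bold_series()].
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  img <- RNifti::asNifti(series$data, datatype = "float")
  img <- RNifti::updateNifti(img, template = list(
    pixdim = c(-1, voxel_sizes(series$affine), series$tr_s, 0, 0, 0)))
  RNifti::sform(img) <- structure(series$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D binary mask NIfTI file
#' @param path Path to a NIfTI-1 file with 3D data containing only 0 and 1.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    abort(sprintf("'%s' is %dD; a mask must be 3D.", path, length(dim(img))))
  brain_mask(array(as.numeric(img), dim(img)), affine = nifti_affine(img))
}

#' Write a mask as NIfTI
#' @param mask A [brain_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                         datatype = "uint8")
  img <- RNifti::updateNifti(img, template = list(
    pixdim = c(-1, voxel_sizes(mask$affine), 1, 0, 0, 0)))
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D statistic or amplitude map as float32 NIfTI
#' @param map An `amplitude_map`, `stat_map`, `fc_map` (z grid written) or
#'   plain 3D array.
#' @param path Output path.
#' @param affine Affine for plain arrays.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, affine = NULL) {
  if (inherits(map, "amplitude_map")) {
    data <- map$data; affine <- map$mask$affine
  } else if (inherits(map, "stat_map")) {
    data <- map$stat; affine <- map$mask$affine
  } else if (inherits(map, "fc_map")) {
    data <- map$z; affine <- map$mask$affine
  } else if (is.array(map) && length(dim(map)) == 3L) {
    data <- map; affine <- affine %||% diag(4)
  } else abort("Unsupported map type.")
  img <- RNifti::asNifti(data, datatype = "float")
  img <- RNifti::updateNifti(img, template = list(
    pixdim = c(-1, voxel_sizes(affine), 1, 0, 0, 0)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an SPM-dialect motion parameter file
#'
#' Six whitespace-separated numeric columns per time point: three
#' translations in mm, then three rotations in radians.
#'
#' @param path Path to an `rp_*.txt`-style file.
#' @return A [motion_trace()].
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 6L)
      abort(sprintf("'%s' line %d has %d columns; expected 6.",
                    path, i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      abort(sprintf("'%s' line %d has non-numeric fields.", path, i))
    vals
  })
  m <- do.call(rbind, rows)
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' Write a motion trace in the SPM rp-file dialect
#' @param motion A [motion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  m <- cbind(motion$translations, motion$rotations)
  utils::write.table(format(m, scientific = FALSE, digits = 8), path,
                     sep = "  ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' All thresholds and acquisition parameters of the end-to-end run, with the
#' pipeline's defaults: TR 2 s, 10 discarded volumes, 0.01-0.08 Hz band,
#' 4 mm FWHM smoothing, 2.0 mm / 2.0 deg motion exclusion limits, voxel
#' p 0.05, corrected alpha 0.05, 1000 Monte-Carlo iterations,
#' 26-connectivity, global-signal regression on.
#'
#' @param cohort_dir Directory holding the cohort (`cohort.tsv`, NIfTI and
#'   motion files, masks).
#' @param out_dir Output directory.
#' @param tr_s,n_discard Acquisition handling.
#' @param low_hz,high_hz Band edges.
#' @param fwhm_mm Smoothing FWHM.
#' @param trans_limit_mm,rot_limit_deg Motion exclusion limits.
#' @param voxel_p,alpha,n_iterations,connectivity Cluster correction.
#' @param seed_roi Name of the ROI mask used as seed / biomarker region.
#' @param fc_groups Groups entering the connectivity branch.
#' @param roc_pairs List of c(positive, negative) group pairs for ROC.
#' @param include_global Global-signal regression flag.
#' @param rng_seed Master seed for the Monte-Carlo null.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir, out_dir,
                            tr_s = 2.0, n_discard = 10L,
                            low_hz = 0.01, high_hz = 0.08,
                            fwhm_mm = 4, trans_limit_mm = 2.0,
                            rot_limit_deg = 2.0, voxel_p = 0.05,
                            alpha = 0.05, n_iterations = 1000L,
                            connectivity = 26, seed_roi = "ba17",
                            fc_groups = c("SUC", "SC", "CON"),
                            roc_pairs = list(c("SUC", "CON"), c("SUC", "SC")),
                            include_global = TRUE, rng_seed = 1L) {
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, tr_s = tr_s,
                 n_discard = as.integer(n_discard),
                 band = band_spec(low_hz, high_hz), fwhm_mm = fwhm_mm,
                 trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg, voxel_p = voxel_p,
                 alpha = alpha, n_iterations = as.integer(n_iterations),
                 connectivity = connectivity, seed_roi = seed_roi,
                 fc_groups = fc_groups, roc_pairs = roc_pairs,
                 include_global = include_global,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$roc_pairs))
    vals$roc_pairs <- lapply(vals$roc_pairs, unlist)
  do.call(pipeline_config, vals)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a cohort directory
#'
#' End-to-end orchestration over an on-disk cohort: motion QC (framewise
#' displacement and exclusion limits), the fALFF branch
#' (discard -> smooth -> detrend -> band-pass -> fALFF -> global-mean
#' normalization), voxelwise group ANOVA and pairwise t-tests with
#' Monte-Carlo cluster-extent correction, the ROI biomarker branch (ROI-mean
#' fALFF, group stats, ROC with AUC/CI/cut-point), and the connectivity
#' branch (discard -> band-pass -> nuisance regression -> seed z-maps,
#' per-group sign maps, pairwise comparisons and the change taxonomy).
#' Every tabular output is written as TSV; thresholds and seeds are logged.
#'
#' @param config A `pipeline_config`.
#' @return Invisible list with every intermediate result bundle.
#' @export
run_pipeline <- function(config) {
  cd <- config$cohort_dir
  tab <- utils::read.table(file.path(cd, "cohort.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  brain <- read_mask(file.path(cd, "brain_mask.nii"))
  seed_roi <- read_mask(file.path(cd, paste0("roi_", config$seed_roi, ".nii")))
  csf <- read_mask(file.path(cd, "roi_csf.nii"))
  wm <- read_mask(file.path(cd, "roi_wm.nii"))

  qc_rows <- list(); falff_maps <- list(); fc_maps <- list()
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    sid <- tab$subject_id[i]
    if (!file.exists(tab$motion_path[i]))
      abort(sprintf("Missing motion file for subject %s.", sid))
    if (!file.exists(tab$bold_path[i]))
      abort(sprintf("Missing BOLD file for subject %s.", sid))
    motion <- read_motion(tab$motion_path[i])
    fdres <- framewise_displacement(motion)
    lim <- exceeds_motion_limits(motion, config$trans_limit_mm,
                                 config$rot_limit_deg)
    qc_rows[[i]] <- tibble::tibble(subject_id = sid, group = tab$group[i],
                                   mean_fd_mm = fdres$mean_fd,
                                   max_trans_mm = lim$max_trans_mm,
                                   max_rot_deg = lim$max_rot_deg,
                                   excluded = lim$exclude)
    keep[i] <- !lim$exclude
    if (lim$exclude) next
    bold <- read_bold(tab$bold_path[i], tr_s = config$tr_s)
    bold <- discard_initial_volumes(bold, config$n_discard)
    # fALFF branch: no band-pass before the spectral ratio -- fALFF needs the
    # full-range spectrum in its denominator (the band enters as the numerator
    # range), otherwise the ratio degenerates to ~1 everywhere.
    b1 <- smooth_gaussian(bold, config$fwhm_mm)
    b1 <- detrend_linear(b1, brain)
    m <- amplitude_map(b1, brain, config$band, kind = "fALFF")
    falff_maps[[sid]] <- normalize_global_mean(m)
    # connectivity branch
    if (tab$group[i] %in% config$fc_groups) {
      b2 <- bandpass_filter(bold, config$band)
      nuis <- suppressWarnings(
        build_nuisance(motion_trace(
          motion$translations[-seq_len(config$n_discard), , drop = FALSE],
          motion$rotations[-seq_len(config$n_discard), , drop = FALSE]),
          b2, csf, wm, include_global = config$include_global,
          global_mask = brain))
      b2 <- regress_nuisance(b2, nuis)
      seed_ts <- seed_timecourse(b2, seed_roi)
      fc_maps[[sid]] <- fc_zmap(b2, seed_ts, brain,
                                seed_label = config$seed_roi)
    }
  }
  qc <- dplyr::bind_rows(qc_rows)
  write_tsv(qc, file.path(config$out_dir, "motion_qc.tsv"))
  tab <- tab[keep, ]

  groups <- split(tab$subject_id, tab$group)
  group_maps <- lapply(groups, function(ids) falff_maps[ids])

  null <- monte_carlo_cluster_null(brain, fwhm_mm = config$fwhm_mm,
                                   voxel_p_threshold = config$voxel_p,
                                   n_iterations = config$n_iterations,
                                   seed = config$rng_seed,
                                   connectivity = config$connectivity)
  anova_map <- voxelwise_anova(group_maps, brain)
  anova_sig <- corrected_significance(anova_map, null, alpha = config$alpha)
  write_tsv(anova_sig$clusters, file.path(config$out_dir, "falff_anova_clusters.tsv"))
  write_map(anova_map, file.path(config$out_dir, "falff_anova_F.nii"))

  pair_tables <- list()
  for (pr in utils::combn(names(group_maps), 2, simplify = FALSE)) {
    tm <- voxelwise_ttest(group_maps[[pr[1]]], group_maps[[pr[2]]], brain)
    cs <- corrected_significance(tm, null, alpha = config$alpha)
    if (nrow(cs$clusters))
      pair_tables[[paste(pr, collapse = "_vs_")]] <-
        dplyr::mutate(cs$clusters, contrast = paste(pr, collapse = "_vs_"),
                      .before = 1)
  }
  if (length(pair_tables))
    write_tsv(dplyr::bind_rows(pair_tables),
              file.path(config$out_dir, "falff_pairwise_clusters.tsv"))

  # ROI biomarker branch
  samples <- roi_samples(falff_maps[tab$subject_id], seed_roi,
                         tab$group)
  write_tsv(samples, file.path(config$out_dir, "roi_falff_samples.tsv"))
  roi_stats <- scalar_group_stats(samples)
  roc_rows <- list()
  for (pr in config$roc_pairs) {
    curve <- roc_curve(samples, pr[1], pr[2])
    ci <- auc_ci(curve)
    yc <- youden_cutpoint(curve)
    ss <- sens_spec_at(samples, pr[1], pr[2], yc$cutpoint)
    roc_rows[[paste(pr, collapse = "_vs_")]] <- tibble::tibble(
      contrast = paste(pr, collapse = "_vs_"),
      auc = ci$auc, se = ci$se, conf.low = ci$conf.low,
      conf.high = ci$conf.high, p.value = ci$p.value,
      cutpoint = yc$cutpoint, sensitivity = ss$sensitivity,
      specificity = ss$specificity, tp = ss$tp, fn = ss$fn, tn = ss$tn,
      fp = ss$fp)
  }
  roc_report <- dplyr::bind_rows(roc_rows)
  write_tsv(roc_report, file.path(config$out_dir, "roi_roc_report.tsv"))

  # connectivity branch group inference
  fc_results <- NULL
  fc_present <- intersect(config$fc_groups, names(groups))
  if (length(fc_present) >= 2) {
    fc_by_group <- lapply(fc_present, function(g)
      fc_maps[intersect(groups[[g]], names(fc_maps))])
    names(fc_by_group) <- fc_present
    fc_null <- monte_carlo_cluster_null(brain, fwhm_mm = 0,
                                        voxel_p_threshold = config$voxel_p,
                                        n_iterations = config$n_iterations,
                                        seed = config$rng_seed + 1L,
                                        connectivity = config$connectivity)
    sign_maps <- lapply(fc_by_group, group_sign_map, cluster_null = fc_null,
                        alpha = config$alpha)
    fc_anova <- voxelwise_anova(fc_by_group, brain)
    fc_anova_sig <- corrected_significance(fc_anova, fc_null,
                                           alpha = config$alpha)
    change_tables <- list()
    for (pr in utils::combn(fc_present, 2, simplify = FALSE)) {
      cmp <- fc_group_compare(fc_by_group[[pr[1]]], fc_by_group[[pr[2]]],
                              brain, fc_null, alpha = config$alpha)
      ch <- classify_cluster_changes(cmp, sign_maps[[pr[1]]],
                                     sign_maps[[pr[2]]])
      if (nrow(ch))
        change_tables[[paste(pr, collapse = "_vs_")]] <-
          dplyr::mutate(ch, contrast = paste(pr, collapse = "_vs_"),
                        .before = 1)
    }
    fc_changes <- dplyr::bind_rows(change_tables)
    write_tsv(fc_changes, file.path(config$out_dir, "fc_change_taxonomy.tsv"))
    write_tsv(fc_anova_sig$clusters,
              file.path(config$out_dir, "fc_anova_clusters.tsv"))
    fc_results <- list(sign_maps = sign_maps, anova = fc_anova,
                       anova_sig = fc_anova_sig, changes = fc_changes,
                       null = fc_null)
  }

  log <- list(config = unclass(config)[setdiff(names(config), "band")],
              band = unclass(config$band),
              k_min_falff = anova_sig$k_min,
              k_min_fc = if (!is.null(fc_results))
                k_min(fc_results$null, config$alpha) else NA,
              n_subjects_kept = nrow(tab),
              excluded_subjects = qc$subject_id[qc$excluded])
  jsonlite::write_json(log, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(qc = qc, falff_maps = falff_maps, anova = anova_map,
                 anova_sig = anova_sig, roi_samples = samples,
                 roi_stats = roi_stats, roc = roc_report, fc = fc_results,
                 null = null))
}
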