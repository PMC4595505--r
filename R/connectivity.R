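#' Assemble the nuisance regressor set
#'
#' Columns are the six rigid-body motion parameters, the mean CSF signal,
#' the mean white-matter signal and (optionally) the global in-brain mean
#' signal.  Every column is centered; constant (all-zero after centering)
#' columns are dropped with a warning.  An intercept is always added at
#' regression time.
#'
#' @param motion A [motion_trace()] with as many rows as the series has
#'   volumes.
#' @param series A [bold_series()].
#' @param csf_mask,wm_mask [brain_mask()] tissue masks on the series grid.
#' @param include_global Include the global (whole brain mask) mean signal
#'   (default TRUE, the convention of this pipeline; contested in the field,
#'   hence switchable).
#' @param global_mask [brain_mask()] used for the global signal.
#' @return Object of class `nuisance_set`: list with `regressors` (t x k
#'   centered matrix with unique column labels) and `dropped`.
#' @export
build_nuisance <- function(motion, series, csf_mask, wm_mask,
                           include_global = TRUE, global_mask = NULL) {
  nt <- dim(series$data)[4]
  if (nrow(motion$translations) != nt)
    abort("Motion trace and series have different numbers of time points.")
  for (nm in c("csf_mask", "wm_mask")) {
    m <- get(nm)
    if (!same_grid(series, m)) abort(sprintf("`%s` is not on the series grid.", nm))
  }
  cols <- cbind(motion$translations, motion$rotations,
                rowMeans(series_matrix(series, csf_mask$data)),
                rowMeans(series_matrix(series, wm_mask$data)))
  labels <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
              "csf", "wm")
  if (include_global) {
    if (is.null(global_mask)) abort("`global_mask` is required when include_global = TRUE.")
    if (!same_grid(series, global_mask)) abort("`global_mask` is not on the series grid.")
    cols <- cbind(cols, rowMeans(series_matrix(series, global_mask$data)))
    labels <- c(labels, "global")
  }
  colnames(cols) <- labels
  cols <- scale(cols, center = TRUE, scale = FALSE)
  zero <- apply(cols, 2, function(x) all(x == 0))
  dropped <- labels[zero]
  if (any(zero)) {
    warn(paste0("Dropping constant nuisance regressor(s): ",
                paste(dropped, collapse = ", ")))
    cols <- cols[, !zero, drop = FALSE]
  }
  structure(list(regressors = cols, dropped = dropped), class = "nuisance_set")
}

#' Regress nuisance signals out of a series
#'
#' Ordinary least-squares residualization against the nuisance set plus an
#' intercept.  Rank-deficient designs are handled by dropping collinear
#' columns (with a warning) before fitting; residuals are orthogonal to
#' every retained regressor.
#'
#' @param x A numeric time series or a [bold_series()] (residualized
#'   voxelwise).
#' @param nuisance A `nuisance_set` from [build_nuisance()].
#' @return Residual series, same type as `x` (provenance gains
#'   `nuisance_regress` for a [bold_series()]).
#' @export
regress_nuisance <- function(x, nuisance) {
  X <- cbind(intercept = 1, nuisance$regressors)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- sort(q$pivot[seq_len(q$rank)])
    warn(paste0("Dropping collinear nuisance column(s): ",
                paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
                      collapse = ", ")))
    q <- qr(X[, keep, drop = FALSE])
  }
  if (inherits(x, "bold_series")) {
    Y <- series_matrix(x)
    if (nrow(Y) != nrow(X)) abort("Series and nuisance set lengths differ.")
    res <- qr.resid(q, Y)
    x$data <- array(t(res), dim(x$data))
    return(add_provenance(x, "nuisance_regress"))
  }
  if (length(x) != nrow(X)) abort("Series and nuisance set lengths differ.")
  as.vector(qr.resid(q, x))
}

#' Mean time course over a seed region
#'
#' @param series A [bold_series()].
#' @param seed_mask A nonempty [brain_mask()] on the series grid.
#' @return Numeric vector, one value per time point.
#' @export
seed_timecourse <- function(series, seed_mask) {
  if (!same_grid(series, seed_mask)) abort("Seed mask is not on the series grid.")
  rowMeans(series_matrix(series, seed_mask$data))
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation between the seed time course and every in-mask voxel
#' series, plus the Fisher r-to-z transform (r clamped at 1 - 1e-7 in
#' magnitude so the seed's own voxels stay finite).  The series must have
#' been band-pass filtered and nuisance-regressed (provenance enforced).
#'
#' @param series A preprocessed [bold_series()].
#' @param seed_ts Seed time course (same length as the series).
#' @param mask A [brain_mask()].
#' @param seed_label Label stored with the map.
#' @return Object of class `fc_map`: list with `r` and `z` 3D grids,
#'   `seed_label`, `mask` and a `qc` tibble of zero-variance voxels.
#' @export
fc_zmap <- function(series, seed_ts, mask, seed_label = "seed") {
  require_provenance(series, c("bandpass", "nuisance_regress"))
  if (!same_grid(series, mask)) abort("Series and mask grids differ.")
  nt <- dim(series$data)[4]
  if (length(seed_ts) != nt) abort("Seed time course length differs from series.")
  X <- series_matrix(series, mask$data)
  sc <- seed_ts - mean(seed_ts)
  Xc <- sweep(X, 2, colMeans(X))
  num <- as.vector(crossprod(Xc, sc))
  den <- sqrt(colSums(Xc^2)) * sqrt(sum(sc^2))
  zero <- den == 0
  r <- ifelse(zero, 0, num / ifelse(zero, 1, den))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  rmap <- array(0, dim3_of(mask)); zmap <- array(0, dim3_of(mask))
  rmap[mask$data] <- r
  zmap[mask$data] <- atanh(r)
  qc <- NULL
  if (any(zero)) {
    ijk <- which(mask$data, arr.ind = TRUE)[zero, , drop = FALSE]
    qc <- tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                         reason = "zero-variance voxel")
  }
  structure(list(r = rmap, z = zmap, seed_label = seed_label, mask = mask,
                 qc = qc), class = "fc_map")
}

#' @export
print.fc_map <- function(x, ...) {
  cat(sprintf("<fc_map> seed '%s'; in-mask r range [%.3f, %.3f]\n",
              x$seed_label, min(x$r[x$mask$data]), max(x$r[x$mask$data])))
  invisible(x)
}

#' Per-group connectivity sign map
#'
#' One-sample t-test of the group's Fisher-z maps against zero, cluster-
#' extent corrected; voxels in surviving positive-t clusters are labeled
#' `positive`, surviving negative-t clusters `negative`, everything else
#' `none`.
#'
#' @param zmaps List of `fc_map` objects (>= 2) on a shared grid.
#' @param cluster_null A `cluster_null` on the same grid.
#' @param voxel_p Voxel-level p threshold (defaults to the null's).
#' @param alpha Corrected alpha (default 0.05).
#' @return Object of class `sign_map`: `sign` (3D array of -1/0/+1) and
#'   `source` (thresholds used).
#' @export
group_sign_map <- function(zmaps, cluster_null, voxel_p = NULL, alpha = 0.05) {
  mask <- zmaps[[1]]$mask
  tmap <- voxelwise_onesample_ttest(zmaps, mask)
  cs <- corrected_significance(tmap, cluster_null,
                               voxel_p_threshold = voxel_p, alpha = alpha)
  sgn <- array(0L, dim3_of(mask))
  sgn[cs$sig & tmap$stat > 0] <- 1L
  sgn[cs$sig & tmap$stat < 0] <- -1L
  structure(list(sign = sgn,
                 source = list(voxel_p = if (is.null(voxel_p))
                   cluster_null$voxel_p_threshold else voxel_p,
                   k_min = cs$k_min, alpha = alpha, n_maps = length(zmaps)),
                 clusters = cs$clusters, mask = mask),
            class = "sign_map")
}

#' @export
print.sign_map <- function(x, ...) {
  cat(sprintf("<sign_map> %d positive, %d negative voxels (k_min %d, voxel p %.3g)\n",
              sum(x$sign == 1L), sum(x$sign == -1L), x$source$k_min,
              x$source$voxel_p))
  invisible(x)
}

#' Compare seed connectivity between two groups
#'
#' Two-sample t-test on the groups' Fisher-z maps followed by cluster-extent
#' correction, typically restricted to the mask where the FC ANOVA was
#' significant.
#'
#' @param zmaps_a,zmaps_b Lists of `fc_map` objects.
#' @param mask A [brain_mask()] restricting the comparison.
#' @param cluster_null A `cluster_null` on the same grid.
#' @param voxel_p Voxel-level p threshold (defaults to the null's).
#' @param alpha Corrected alpha.
#' @return List with `stat_map`, `clusters` (surviving cluster table) and
#'   `sig` (3D logical array).
#' @export
fc_group_compare <- function(zmaps_a, zmaps_b, mask, cluster_null,
                             voxel_p = NULL, alpha = 0.05) {
  tmap <- voxelwise_ttest(zmaps_a, zmaps_b, mask)
  cs <- corrected_significance(tmap, cluster_null,
                               voxel_p_threshold = voxel_p, alpha = alpha)
  list(stat_map = tmap, clusters = cs$clusters, sig = cs$sig,
       k_min = cs$k_min, connectivity = cluster_null$connectivity)
}

#' Classify a connectivity change between two groups
#'
#' Taxonomy of seed-connectivity differences.  When both groups show the
#' same connectivity sign, the change is an increase or decrease of that
#' sign's magnitude ("increased" means the shared-sign magnitude is larger
#' in group A: larger z for positive connectivity, more negative z for
#' negative connectivity).  When the signs differ, the label gives the
#' direction of the difference: `positive_change` if group A is shifted
#' toward positive connectivity relative to group B, `negative_change`
#' otherwise.
#'
#' @param sign_a,sign_b Connectivity sign in each group: `"positive"`,
#'   `"negative"` or `"none"` (at most one may be `"none"`).
#' @param t_direction `"a_greater"` or `"b_greater"`: the sign of the
#'   group-difference t statistic in z units.
#' @return One of `positive_increased`, `positive_decreased`,
#'   `negative_increased`, `negative_decreased`, `positive_change`,
#'   `negative_change`.
#' @export
classify_change <- function(sign_a, sign_b,
                            t_direction = c("a_greater", "b_greater")) {
  t_direction <- match.arg(t_direction)
  ok <- c("positive", "negative", "none")
  if (!sign_a %in% ok || !sign_b %in% ok)
    abort("Signs must be 'positive', 'negative' or 'none'.")
  if (sign_a == "none" && sign_b == "none")
    abort("Both signs are 'none': no classifiable connectivity difference.")
  a_greater <- t_direction == "a_greater"
  if (sign_a == sign_b) {
    if (sign_a == "positive")
      return(if (a_greater) "positive_increased" else "positive_decreased")
    return(if (a_greater) "negative_decreased" else "negative_increased")
  }
  if (a_greater) "positive_change" else "negative_change"
}

# Logical voxel array per surviving-cluster table row, matched through the
# label at the row's peak voxel; positive and negative survivors are labeled
# separately (they may touch without being one cluster).
cluster_voxel_sets <- function(compare) {
  cl <- compare$clusters
  conn <- compare$connectivity %||% 26
  lab_pos <- label_clusters(compare$sig & compare$stat_map$stat > 0,
                            connectivity = conn, stat = compare$stat_map$stat)
  lab_neg <- label_clusters(compare$sig & compare$stat_map$stat < 0,
                            connectivity = conn, stat = compare$stat_map$stat)
  lapply(seq_len(nrow(cl)), function(i) {
    lab <- if (cl$sign[i] == "positive") lab_pos$labels else lab_neg$labels
    at_peak <- lab[cl$peak_i[i], cl$peak_j[i], cl$peak_k[i]]
    lab == at_peak & lab > 0
  })
}

#' Overlap of each surviving cluster with a reference region
#'
#' Counts, per cluster of a [fc_group_compare()] result (or any result with
#' the same shape), how many of its voxels fall inside a reference region
#' mask — useful for matching data-driven clusters to anatomical or
#' ground-truth regions, which a peak coordinate alone does unreliably.
#'
#' @param compare Result of [fc_group_compare()].
#' @param region A [brain_mask()] or 3D logical array.
#' @return Tibble: cluster_id, size_voxels, n_overlap, pct_of_region.
#' @export
cluster_region_overlap <- function(compare, region) {
  if (inherits(region, "brain_mask")) region <- region$data
  cl <- compare$clusters
  vox_sets <- cluster_voxel_sets(compare)
  tibble::tibble(
    cluster_id = cl$cluster_id,
    size_voxels = cl$size_voxels,
    n_overlap = vapply(vox_sets, function(v) sum(v & region), 0L),
    pct_of_region = 100 * vapply(vox_sets, function(v) sum(v & region), 0L) /
      sum(region))
}

#' Classify every surviving cluster of a group comparison
#'
#' For each cluster surviving in [fc_group_compare()], reads the modal
#' connectivity sign of the cluster's voxels from each group's sign map, the
#' t direction from the cluster's peak statistic, and applies
#' [classify_change()].
#'
#' @param compare Result of [fc_group_compare()].
#' @param sign_map_a,sign_map_b `sign_map` objects for the two groups.
#' @return Tibble: cluster_id, size_voxels, sign_a, sign_b, t_direction,
#'   label (NA when both modal signs are `none`).
#' @export
classify_cluster_changes <- function(compare, sign_map_a, sign_map_b) {
  cl <- compare$clusters
  if (!nrow(cl)) {
    return(tibble::tibble(cluster_id = integer(), size_voxels = integer(),
                          sign_a = character(), sign_b = character(),
                          t_direction = character(), label = character()))
  }
  vox_sets <- cluster_voxel_sets(compare)
  modal_sign <- function(sgn_arr, voxels) {
    v <- sgn_arr[voxels]
    nz <- v[v != 0]
    if (!length(nz)) return("none")
    if (sum(nz > 0) >= sum(nz < 0)) "positive" else "negative"
  }
  out <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    vox <- vox_sets[[i]]
    sa <- modal_sign(sign_map_a$sign, vox)
    sb <- modal_sign(sign_map_b$sign, vox)
    dir <- if (cl$peak_stat[i] >= 0) "a_greater" else "b_greater"
    lab <- if (sa == "none" && sb == "none") NA_character_
           else classify_change(sa, sb, dir)
    out[[i]] <- tibble::tibble(cluster_id = cl$cluster_id[i],
                               size_voxels = cl$size_voxels[i],
                               sign_a = sa, sign_b = sb,
                               t_direction = dir, label = lab)
  }
  dplyr::bind_rows(out)
}
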