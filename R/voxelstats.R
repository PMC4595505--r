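maps_matrix <- function(maps, mask, require_normalized = FALSE) {
  cols <- lapply(maps, function(m) {
    if (inherits(m, "amplitude_map")) {
      if (require_normalized && !isTRUE(m$normalized))
        abort("All amplitude maps must be normalized (see normalize_global_mean).")
      m <- m$data
    } else if (inherits(m, "fc_map")) {
      m <- m$z
    }
    if (!identical(dim(m), dim3_of(mask))) abort("Map grid does not match mask.")
    m[mask$data]
  })
  do.call(cbind, cols)
}

#' Voxelwise one-way ANOVA across groups
#'
#' Per-voxel one-way ANOVA F statistic and upper-tail p value across k
#' groups of subject maps, with df (k - 1, N - k).  Voxels with zero
#' within- and between-group variance get F = 0, p = 1.
#'
#' @param group_maps Named list: group label -> list of normalized
#'   `amplitude_map` objects (or plain 3D arrays / `fc_map`s).
#' @param mask A [brain_mask()] shared by all maps.
#' @return A `stat_map` of kind `anova_F`.
#' @export
voxelwise_anova <- function(group_maps, mask) {
  if (length(group_maps) < 2L) abort("Need at least 2 groups.")
  sizes <- vapply(group_maps, length, 1L)
  if (any(sizes < 2L))
    abort(sprintf("Group '%s' has fewer than 2 subjects.",
                  names(group_maps)[which(sizes < 2L)[1]]))
  req_norm <- inherits(group_maps[[1]][[1]], "amplitude_map")
  X <- maps_matrix(unlist(group_maps, recursive = FALSE), mask,
                   require_normalized = req_norm)
  g <- rep(names(group_maps), sizes)
  N <- ncol(X); k <- length(group_maps)
  grand <- rowMeans(X)
  ssb <- 0; ssw <- 0
  for (lab in names(group_maps)) {
    sel <- g == lab
    n_g <- sum(sel)
    m_g <- rowMeans(X[, sel, drop = FALSE])
    ssb <- ssb + n_g * (m_g - grand)^2
    ssw <- ssw + rowSums((X[, sel, drop = FALSE] - m_g)^2)
  }
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  F[ssw == 0 & ssb == 0] <- 0
  F[ssw == 0 & ssb > 0] <- Inf
  p <- pf(F, k - 1, N - k, lower.tail = FALSE)
  stat <- array(0, dim3_of(mask)); pmap <- array(1, dim3_of(mask))
  stat[mask$data] <- F; pmap[mask$data] <- p
  new_stat_map(stat, pmap, df = c(df1 = k - 1, df2 = N - k), mask = mask,
               kind = "anova_F")
}

#' Voxelwise two-sample t-test
#'
#' Two-sided pooled-variance (Student) t per voxel; positive t means group A
#' exceeds group B.  Voxels with zero pooled variance get t = 0, p = 1 and
#' are listed in the map's QC log.
#'
#' @param maps_a,maps_b Lists of subject maps for the two groups (each >= 2).
#' @param mask A [brain_mask()].
#' @return A `stat_map` of kind `two_sample_t` with a `qc` element.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask) {
  if (length(maps_a) < 2L || length(maps_b) < 2L)
    abort("Each group needs at least 2 subjects.")
  req_norm <- inherits(maps_a[[1]], "amplitude_map")
  A <- maps_matrix(maps_a, mask, require_normalized = req_norm)
  B <- maps_matrix(maps_b, mask, require_normalized = req_norm)
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  ss1 <- rowSums((A - m1)^2); ss2 <- rowSums((B - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  zero <- sp2 == 0
  t[zero] <- 0
  p <- 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE)
  p[zero] <- 1
  stat <- array(0, dim3_of(mask)); pmap <- array(1, dim3_of(mask))
  stat[mask$data] <- t; pmap[mask$data] <- p
  out <- new_stat_map(stat, pmap, df = c(df = n1 + n2 - 2), mask = mask,
                      kind = "two_sample_t")
  if (any(zero)) {
    ijk <- which(mask$data, arr.ind = TRUE)[zero, , drop = FALSE]
    out$qc <- tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                             reason = "zero pooled variance")
  }
  out
}

#' Voxelwise one-sample t-test against a constant
#'
#' @param maps List of subject maps (>= 2).
#' @param mask A [brain_mask()].
#' @param mu Null value (default 0).
#' @return A `stat_map` of kind `one_sample_t`.
#' @export
voxelwise_onesample_ttest <- function(maps, mask, mu = 0) {
  if (length(maps) < 2L) abort("Need at least 2 maps.")
  X <- maps_matrix(maps, mask)
  n <- ncol(X)
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (n - 1))
  t <- (m - mu) / (s / sqrt(n))
  zero <- s == 0
  t[zero & m == mu] <- 0
  t[zero & m != mu] <- sign(m - mu)[zero & m != mu] * Inf
  p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
  stat <- array(0, dim3_of(mask)); pmap <- array(1, dim3_of(mask))
  stat[mask$data] <- t; pmap[mask$data] <- p
  new_stat_map(stat, pmap, df = c(df = n - 1), mask = mask,
               kind = "one_sample_t")
}

#' Label connected clusters of a binary map
#'
#' Connected components under a 6-, 18- or 26-neighbourhood, sized in voxels
#' and mm^3, with deterministic ordering by size (descending) then
#' lexicographic peak coordinate.  When a statistic map is supplied, each
#' cluster's peak is the voxel maximizing |stat|, and its world coordinates
#' are reported through the affine.
#'
#' @param binary 3D logical/0-1 array (or [brain_mask()]).
#' @param connectivity One of 6, 18, 26 (default 26).
#' @param affine Optional 4x4 affine for mm^3 sizes and world coordinates
#'   (taken from `binary` when it is a mask).
#' @param stat Optional 3D statistic array used for peaks and signs.
#' @return List with `labels` (3D integer array, 0 = background) and `table`
#'   (tibble: cluster_id, size_voxels, size_mm3, peak_stat, peak i/j/k,
#'   peak x/y/z in mm, sign).
#' @export
label_clusters <- function(binary, connectivity = 26, affine = NULL,
                           stat = NULL) {
  if (!connectivity %in% c(6, 18, 26))
    abort("`connectivity` must be 6, 18 or 26.")
  if (inherits(binary, "brain_mask")) {
    if (is.null(affine)) affine <- binary$affine
    binary <- binary$data
  }
  if (!is.array(binary) || length(dim(binary)) != 3L)
    abort("`binary` must be a 3D array.")
  dims <- dim(binary)
  labels <- .label_components_cpp(as.logical(binary), as.integer(dims),
                                  as.integer(connectivity))
  n_cl <- max(labels)
  vox_vol <- if (is.null(affine)) NA_real_ else voxel_volume_mm3(affine)
  if (n_cl == 0L) {
    return(list(labels = labels, table = empty_cluster_table()))
  }
  rows <- vector("list", n_cl)
  for (cl in seq_len(n_cl)) {
    ijk <- which(labels == cl, arr.ind = TRUE)
    if (!is.null(stat)) {
      sv <- stat[cbind(ijk)]
      pk <- which.max(abs(sv))
      peak_stat <- sv[pk]
    } else {
      ord <- order(ijk[, 1], ijk[, 2], ijk[, 3])
      pk <- ord[1]
      peak_stat <- NA_real_
    }
    rows[[cl]] <- list(old_id = cl, size_voxels = nrow(ijk),
                       peak_stat = peak_stat,
                       pi = ijk[pk, 1], pj = ijk[pk, 2], pk_ = ijk[pk, 3])
  }
  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  ord <- order(-tab$size_voxels, tab$pi, tab$pj, tab$pk_)
  tab <- tab[ord, ]
  relabel <- integer(n_cl)
  relabel[tab$old_id] <- seq_len(n_cl)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  world <- if (is.null(affine)) matrix(NA_real_, n_cl, 3)
           else voxel_to_world(cbind(tab$pi, tab$pj, tab$pk_), affine)
  table <- tibble::tibble(
    cluster_id = seq_len(n_cl),
    size_voxels = tab$size_voxels,
    size_mm3 = tab$size_voxels * vox_vol,
    peak_stat = tab$peak_stat,
    peak_i = tab$pi, peak_j = tab$pj, peak_k = tab$pk_,
    peak_x_mm = world[, 1], peak_y_mm = world[, 2], peak_z_mm = world[, 3],
    sign = ifelse(is.na(tab$peak_stat), NA_character_,
                  ifelse(tab$peak_stat >= 0, "positive", "negative"))
  )
  list(labels = labels, table = table)
}

empty_cluster_table <- function() {
  tibble::tibble(cluster_id = integer(), size_voxels = integer(),
                 size_mm3 = numeric(), peak_stat = numeric(),
                 peak_i = integer(), peak_j = integer(), peak_k = integer(),
                 peak_x_mm = numeric(), peak_y_mm = numeric(),
                 peak_z_mm = numeric(), sign = character())
}

#' Monte-Carlo null distribution of maximum cluster size
#'
#' AlphaSim-style simulation: per iteration the grid is filled with
#' independent standard Gaussian noise, smoothed to the stated FWHM,
#' re-standardized within the mask, thresholded two-sidedly at the voxel
#' p threshold, and the maximal cluster size (positive and negative voxels
#' clustered separately, as in the data path) is recorded.  The minimum
#' surviving cluster size for a corrected alpha is derived from the
#' distribution of these maxima.
#'
#' @param mask A [brain_mask()].
#' @param fwhm_mm Smoothness of the simulated noise (mm); sigma below 0.1
#'   voxel is treated as unsmoothed with a warning.
#' @param voxel_p_threshold Two-sided voxel-level p threshold.
#' @param n_iterations Number of Monte-Carlo iterations (>= 100).
#' @param seed RNG seed.
#' @param connectivity Cluster connectivity (6, 18, 26); must match the data
#'   thresholding.
#' @return An object of class `cluster_null`.
#' @export
monte_carlo_cluster_null <- function(mask, fwhm_mm = 4,
                                     voxel_p_threshold = 0.05,
                                     n_iterations = 1000L, seed = 1L,
                                     connectivity = 26) {
  if (n_iterations < 100L) abort("Need at least 100 iterations.")
  if (!connectivity %in% c(6, 18, 26))
    abort("`connectivity` must be 6, 18 or 26.")
  dims <- dim3_of(mask)
  vs <- voxel_sizes(mask$affine)
  sigmas <- fwhm_mm / (2.3548 * vs)
  do_smooth <- any(sigmas >= 0.1)
  if (!do_smooth && fwhm_mm > 0)
    warn(sprintf("FWHM %.3g mm is under 0.1 voxel on every axis; proceeding unsmoothed.",
                 fwhm_mm))
  zcrit <- qnorm(1 - voxel_p_threshold / 2)
  inmask <- mask$data
  maxima <- integer(n_iterations)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      noise <- array(rnorm(prod(dims)), dims)
      if (do_smooth) noise <- smooth_volume(noise, sigmas)
      v <- noise[inmask]
      z <- array(0, dims)
      z[inmask] <- (v - mean(v)) / sd(v)
      mx <- 0L
      for (b in list(z > zcrit & inmask, z < -zcrit & inmask)) {
        if (any(b)) {
          lab <- .label_components_cpp(b, as.integer(dims),
                                       as.integer(connectivity))
          if (max(lab) > 0L) mx <- max(mx, max(tabulate(lab[lab > 0L])))
        }
      }
      maxima[it] <- mx
    }
  })
  structure(list(voxel_p_threshold = voxel_p_threshold, fwhm_mm = fwhm_mm,
                 n_iterations = as.integer(n_iterations),
                 max_cluster_sizes = maxima, connectivity = connectivity,
                 mask_dim = dims, voxel_sizes = vs, seed = as.integer(seed)),
            class = "cluster_null")
}

#' Minimum surviving cluster size for a corrected alpha
#'
#' The ceiling((1 - alpha) * n)-th order statistic of the per-iteration
#' maximum cluster sizes, plus one: clusters strictly larger than this have
#' family-wise corrected p below alpha.
#'
#' @param null A `cluster_null`.
#' @param alpha Corrected significance level (default 0.05).
#' @return Integer minimum cluster size (voxels).
#' @export
k_min <- function(null, alpha = 0.05) {
  if (!inherits(null, "cluster_null")) abort("`null` must be a cluster_null.")
  s <- sort(null$max_cluster_sizes)
  s[ceiling((1 - alpha) * null$n_iterations)] + 1L
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf("<cluster_null> %d iterations, voxel p %.3g, FWHM %.3g mm, %d-connectivity\n",
              x$n_iterations, x$voxel_p_threshold, x$fwhm_mm, x$connectivity))
  cat(sprintf("  k_min: %d (alpha 0.05), %d (alpha 0.01)\n",
              k_min(x, 0.05), k_min(x, 0.01)))
  invisible(x)
}

#' Cluster-extent corrected significance
#'
#' Thresholds a statistic map two-sidedly at the voxel p threshold, labels
#' positive and negative supra-threshold voxels separately, and keeps
#' clusters strictly larger than the Monte-Carlo `k_min` at the requested
#' corrected alpha.
#'
#' @param stat_map A `stat_map`.
#' @param cluster_null A `cluster_null` computed on the same grid and
#'   connectivity.
#' @param voxel_p_threshold Voxel-level threshold (defaults to the null's).
#' @param alpha Corrected (family-wise) alpha (default 0.05).
#' @return List with `clusters` (tibble of survivors), `sig` (3D logical
#'   significance array), `k_min` and `alpha`.
#' @export
corrected_significance <- function(stat_map, cluster_null,
                                   voxel_p_threshold = NULL, alpha = 0.05) {
  if (!identical(dim3_of(stat_map$mask), cluster_null$mask_dim))
    abort("Statistic map grid does not match the cluster null grid.")
  if (is.null(voxel_p_threshold))
    voxel_p_threshold <- cluster_null$voxel_p_threshold
  km <- k_min(cluster_null, alpha)
  inmask <- stat_map$mask$data
  supra <- (stat_map$p < voxel_p_threshold) & inmask
  sig <- array(FALSE, dim(supra))
  tables <- list()
  for (sgn in c(1, -1)) {
    b <- supra & (sign(stat_map$stat) == sgn)
    if (!any(b)) next
    lc <- label_clusters(b, connectivity = cluster_null$connectivity,
                         affine = stat_map$mask$affine, stat = stat_map$stat)
    keep <- lc$table$size_voxels > km
    if (any(keep)) {
      kept_ids <- lc$table$cluster_id[keep]
      sig <- sig | array(lc$labels %in% kept_ids, dim(sig))
      tables[[length(tables) + 1L]] <- lc$table[keep, ]
    }
  }
  clusters <- if (length(tables)) dplyr::bind_rows(tables)
              else empty_cluster_table()
  if (nrow(clusters)) {
    ord <- order(-clusters$size_voxels, clusters$peak_i, clusters$peak_j,
                 clusters$peak_k)
    clusters <- clusters[ord, ]
    clusters$cluster_id <- seq_len(nrow(clusters))
  }
  list(clusters = clusters, sig = sig, k_min = km, alpha = alpha)
}

#' Spatial overlap between two binary maps
#'
#' @param mask_a,mask_b [brain_mask()] objects or 3D logical arrays on the
#'   same grid.
#' @return One-row tibble: sizes of A, B, intersection and union (voxels)
#'   and the three percentages (of A, of B, of the union).
#' @export
overlap_stats <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "brain_mask")) mask_a$data else mask_a
  b <- if (inherits(mask_b, "brain_mask")) mask_b$data else mask_b
  if (!identical(dim(a), dim(b))) abort("Masks are on different grids.")
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  nu <- na + nb - ni
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  tibble::tibble(size_a = na, size_b = nb, size_intersection = ni,
                 size_union = nu,
                 pct_of_a = pct(ni, na), pct_of_b = pct(ni, nb),
                 pct_of_union = pct(ni, nu))
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA from per-group sizes, means and standard
#' deviations: SS_between = sum n_i (m_i - grand mean)^2, SS_within =
#' sum (n_i - 1) s_i^2, F with df (k - 1, N - k) and upper-tail p.
#'
#' @param ns Integer vector of group sizes (each >= 2).
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group standard deviations (>= 0).
#' @return One-row tibble: statistic, df, df.residual, p.value.
#' @export
summary_stat_anova <- function(ns, means, sds) {
  if (length(ns) != length(means) || length(ns) != length(sds))
    abort("ns, means and sds must have equal length.")
  if (any(ns < 2)) abort("All group sizes must be >= 2.")
  if (any(sds < 0)) abort("Standard deviations must be nonnegative.")
  N <- sum(ns); k <- length(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  F <- if (ssb == 0) 0 else (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(statistic = F, df = k - 1, df.residual = N - k,
                 p.value = pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-squared test of a contingency table
#'
#' Pearson chi-squared without continuity correction, df = (r - 1)(c - 1).
#'
#' @param counts Matrix of nonnegative integer counts with positive row and
#'   column sums.
#' @return One-row tibble: statistic, df, p.value.
#' @export
contingency_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort("All row and column sums must be positive.")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p.value = unname(res$p.value))
}
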