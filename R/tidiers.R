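#' Tidy an ROC curve into its threshold sweep
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble: threshold, sensitivity, one_minus_specificity, specificity.
#' @export
tidy.roc_curve <- function(x, ...) {
  dplyr::mutate(x$points, specificity = 1 - .data$one_minus_specificity)
}

#' One-row summary of an ROC curve
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return Tibble: positive/negative labels, n per group, auc, se, CI,
#'   p.value, Youden cutpoint with its sensitivity/specificity.
#' @export
glance.roc_curve <- function(x, ...) {
  ci <- auc_ci(x)
  yc <- youden_cutpoint(x)
  tibble::tibble(positive_label = x$positive_label,
                 negative_label = x$negative_label,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 auc = ci$auc, se = ci$se, conf.low = ci$conf.low,
                 conf.high = ci$conf.high, p.value = ci$p.value,
                 cutpoint = yc$cutpoint, sensitivity = yc$sensitivity,
                 specificity = yc$specificity)
}

#' Tidy a frequency spectrum
#' @param x A `freq_spectrum`.
#' @param ... Unused.
#' @return Tibble: freq_hz, amplitude.
#' @export
tidy.freq_spectrum <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs_hz, amplitude = x$amplitude)
}

#' Tidy a Monte-Carlo cluster null
#' @param x A `cluster_null`.
#' @param ... Unused.
#' @return Tibble: iteration, max_cluster_size.
#' @export
tidy.cluster_null <- function(x, ...) {
  tibble::tibble(iteration = seq_len(x$n_iterations),
                 max_cluster_size = x$max_cluster_sizes)
}

#' One-row summary of a Monte-Carlo cluster null
#' @param x A `cluster_null`.
#' @param ... Unused.
#' @return Tibble with the simulation settings and k_min at alpha 0.05/0.01.
#' @export
glance.cluster_null <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations,
                 voxel_p_threshold = x$voxel_p_threshold,
                 fwhm_mm = x$fwhm_mm, connectivity = x$connectivity,
                 k_min_alpha05 = k_min(x, 0.05),
                 k_min_alpha01 = k_min(x, 0.01))
}

#' Tidy a statistic map into a voxel table
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return Tibble: i, j, k, statistic, p.value (in-mask voxels only).
#' @export
tidy.stat_map <- function(x, ...) {
  ijk <- which(x$mask$data, arr.ind = TRUE)
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 statistic = x$stat[x$mask$data],
                 p.value = x$p[x$mask$data])
}

#' Tidy an amplitude map into a voxel table
#' @param x An `amplitude_map`.
#' @param ... Unused.
#' @return Tibble: i, j, k, value (in-mask voxels only).
#' @export
tidy.amplitude_map <- function(x, ...) {
  ijk <- which(x$mask$data, arr.ind = TRUE)
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 value = x$data[x$mask$data])
}
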