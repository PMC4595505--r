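#' Plot an ROC curve
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$one_minus_specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("%s vs %s (AUC %.3f)",
                                  object$positive_label,
                                  object$negative_label, roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot the Monte-Carlo null distribution of maximum cluster size
#' @param object A `cluster_null`.
#' @param alpha Corrected alpha marked on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_null <- function(object, alpha = 0.05, ...) {
  km <- k_min(object, alpha)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$max_cluster_size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = km, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "Maximum cluster size per iteration (voxels)",
                  y = "Iterations",
                  title = sprintf("Cluster null: k_min = %d at alpha %.2g",
                                  km, alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a one-sided amplitude spectrum
#' @param object A `freq_spectrum`.
#' @param band Optional [band_spec()] shaded on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.freq_spectrum <- function(object, band = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$freq_hz, y = .data$amplitude))
  if (!is.null(band))
    p <- p + ggplot2::annotate("rect", xmin = band$low_hz, xmax = band$high_hz,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Amplitude (sqrt power)") +
    ggplot2::theme_minimal()
}

#' Plot one axial slice of a 3D map
#' @param map An `amplitude_map`, `stat_map`, `fc_map` or 3D array.
#' @param k Slice index along the third axis (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
plot_map_slice <- function(map, k = NULL, ...) {
  data <- if (inherits(map, "amplitude_map")) map$data
          else if (inherits(map, "stat_map")) map$stat
          else if (inherits(map, "fc_map")) map$z
          else map
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("Need a 3D map.")
  if (is.null(k)) k <- ceiling(dim(data)[3] / 2)
  sl <- data[, , k]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Slice k = %d", k), x = "i", y = "j") +
    ggplot2::theme_minimal()
}
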