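#' Mean map value within an ROI
#'
#' Arithmetic mean of an amplitude map over the ROI voxels.  If part of the
#' ROI falls outside the map's brain mask, a warning is issued and the mean
#' is taken over the intersection.
#'
#' @param map An `amplitude_map`.
#' @param roi A [brain_mask()] on the same grid.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, roi) {
  if (!identical(dim(map$data), dim3_of(roi))) abort("ROI grid does not match map.")
  sel <- roi$data
  outside <- sel & !map$mask$data
  if (any(outside)) {
    warn(sprintf("%d ROI voxels fall outside the brain mask; using the intersection.",
                 sum(outside)))
    sel <- sel & map$mask$data
    if (!any(sel)) abort("ROI does not intersect the brain mask.")
  }
  mean(map$data[sel])
}

#' Extract per-subject ROI-mean values into a sample table
#'
#' @param maps Named list of `amplitude_map` objects (names = subject ids).
#' @param roi A [brain_mask()].
#' @param groups Character vector of group labels aligned with `maps`.
#' @return Tibble with columns subject_id, group, value.
#' @export
roi_samples <- function(maps, roi, groups) {
  if (length(maps) != length(groups)) abort("`maps` and `groups` lengths differ.")
  ids <- names(maps)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(maps))
  tibble::tibble(subject_id = ids, group = as.character(groups),
                 value = vapply(maps, roi_mean, 0, roi = roi))
}

#' Group statistics on a scalar ROI measure
#'
#' One-way ANOVA across all groups plus Student (pooled-variance, two-sided)
#' two-sample t-tests for the requested pairs.  Pairwise p values are
#' reported raw, without multiplicity adjustment.
#'
#' @param samples Tibble with columns `group` and `value` (each group >= 2).
#' @param pairs Optional list of length-2 character vectors of group pairs;
#'   defaults to all pairs.
#' @return List with `anova` (one-row tibble: statistic, df, df.residual,
#'   p.value) and `pairwise` (tibble: group_a, group_b, statistic, df,
#'   p.value).
#' @export
scalar_group_stats <- function(samples, pairs = NULL) {
  tab <- table(samples$group)
  if (any(tab < 2)) abort("Every group needs at least 2 samples.")
  groups <- names(tab)
  ns <- as.integer(tab)
  means <- vapply(groups, function(g) mean(samples$value[samples$group == g]), 0)
  sds <- vapply(groups, function(g) sd(samples$value[samples$group == g]), 0)
  anova <- if (all(sds == 0) && length(unique(means)) == 1L) {
    tibble::tibble(statistic = 0, df = length(groups) - 1,
                   df.residual = sum(ns) - length(groups), p.value = 1)
  } else summary_stat_anova(ns, means, sds)
  if (is.null(pairs)) pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    if (!all(pr %in% groups))
      abort(sprintf("Unknown group label '%s'.", setdiff(pr, groups)[1]))
    a <- samples$value[samples$group == pr[1]]
    b <- samples$value[samples$group == pr[2]]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      p <- 2 * pt(abs(tstat), length(a) + length(b) - 2, lower.tail = FALSE)
    }
    tibble::tibble(group_a = pr[1], group_b = pr[2], statistic = tstat,
                   df = length(a) + length(b) - 2, p.value = p)
  })
  list(anova = anova, pairwise = dplyr::bind_rows(pw))
}

#' Empirical ROC curve of a scalar classifier
#'
#' Threshold sweep over all distinct sample values plus infinite sentinels,
#' with the convention score > threshold => positive call.  The curve starts
#' at (0, 0) and ends at (1, 1); sensitivity is nondecreasing along the
#' sweep.
#'
#' @param samples Tibble with columns `group` and `value`.
#' @param positive_group,negative_group Group labels.
#' @return Object of class `roc_curve`: list with `points` (tibble:
#'   threshold, sensitivity, one_minus_specificity), `positive_label`,
#'   `n_pos`, `n_neg` and the raw scores.
#' @export
roc_curve <- function(samples, positive_group, negative_group) {
  labs <- unique(samples$group)
  for (g in c(positive_group, negative_group))
    if (!g %in% labs) abort(sprintf("Unknown group label '%s'.", g))
  pos <- samples$value[samples$group == positive_group]
  neg <- samples$value[samples$group == negative_group]
  if (!length(pos) || !length(neg)) abort("Both groups need at least 1 sample.")
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(ct) mean(pos > ct), 0)
  fpr <- vapply(thr, function(ct) mean(neg > ct), 0)
  structure(list(points = tibble::tibble(threshold = thr, sensitivity = sens,
                                         one_minus_specificity = fpr),
                 positive_label = positive_group,
                 negative_label = negative_group,
                 n_pos = length(pos), n_neg = length(neg),
                 pos_scores = pos, neg_scores = neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %s (n=%d) vs %s (n=%d); AUC %.3f\n",
              x$positive_label, x$n_pos, x$negative_label, x$n_neg,
              roc_auc(x)))
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#' @param curve A `roc_curve`.
#' @return AUC in [0, 1] (ties between groups count one half).
#' @export
roc_auc <- function(curve) {
  p <- curve$points
  sum(diff(p$one_minus_specificity) *
        (utils::head(p$sensitivity, -1) + utils::tail(p$sensitivity, -1)) / 2)
}

#' AUC with Hanley-McNeil standard error and confidence interval
#'
#' Normal-approximation CI around the trapezoidal AUC using the
#' Hanley-McNeil standard error.  The interval is deliberately not clipped
#' to [0, 1].  The p value tests AUC = 0.5 with the same standard error.
#'
#' @param curve A `roc_curve` with at least 2 samples per group.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: auc, se, conf.low, conf.high, p.value.
#' @export
auc_ci <- function(curve, level = 0.95) {
  if (curve$n_pos < 2L || curve$n_neg < 2L)
    abort("Need at least 2 samples per group for a confidence interval.")
  A <- roc_auc(curve)
  se <- hanley_mcneil_se(A, curve$n_pos, curve$n_neg)
  zq <- qnorm(1 - (1 - level) / 2)
  pz <- if (se > 0) 2 * stats::pnorm(abs(A - 0.5) / se, lower.tail = FALSE) else 0
  tibble::tibble(auc = A, se = se, conf.low = A - zq * se,
                 conf.high = A + zq * se, p.value = pz)
}

#' Hanley-McNeil standard error of an AUC
#' @param auc Area under the curve.
#' @param n_pos,n_neg Group sizes.
#' @return Standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Youden-index optimal cut-point
#'
#' The threshold maximizing sensitivity + specificity - 1, with ties broken
#' toward the lower threshold.
#'
#' @param curve A `roc_curve`.
#' @return One-row tibble: cutpoint, sensitivity, specificity, youden.
#' @export
youden_cutpoint <- function(curve) {
  p <- curve$points
  j <- p$sensitivity - p$one_minus_specificity
  jmax <- max(j)
  cand <- which(j == jmax)
  best <- cand[which.min(p$threshold[cand])]
  tibble::tibble(cutpoint = p$threshold[best],
                 sensitivity = p$sensitivity[best],
                 specificity = 1 - p$one_minus_specificity[best],
                 youden = jmax)
}

#' Sensitivity and specificity at a fixed cut-point
#'
#' Positive call iff value > cut (strict).
#'
#' @param samples Tibble with columns `group` and `value`.
#' @param positive_group,negative_group Group labels.
#' @param cut Finite threshold.
#' @return One-row tibble: cut, tp, fn, tn, fp, sensitivity, specificity.
#' @export
sens_spec_at <- function(samples, positive_group, negative_group, cut) {
  if (!is.finite(cut)) abort("`cut` must be finite.")
  pos <- samples$value[samples$group == positive_group]
  neg <- samples$value[samples$group == negative_group]
  tp <- sum(pos > cut); fn <- sum(pos <= cut)
  tn <- sum(neg <= cut); fp <- sum(neg > cut)
  tibble::tibble(cut = cut, tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}
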