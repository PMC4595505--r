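# Independent oracles used across tests. These deliberately re-implement the
# checked quantities by different routes (direct summation, flood fill,
# rank statistics) and must stay independent of the package internals.

# fALFF by direct DFT summation: sqrt of raw periodogram values, summed.
falff_oracle <- function(ts, tr_s, low = 0.01, high = 0.08) {
  n <- length(ts)
  amp <- Mod(fft(ts))
  half <- n %/% 2
  freqs <- (0:half) / (n * tr_s)
  amp <- amp[1:(half + 1)]
  inband <- freqs >= low - 1e-12 & freqs <= high + 1e-12
  keep <- freqs > 0
  sum(amp[inband & keep]) / sum(amp[keep])
}

# Brute-force 3D connected components via breadth-first flood fill in R.
flood_fill_labels <- function(binary, connectivity) {
  d <- dim(binary)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  if (connectivity == 6) offsets <- offsets[rowSums(abs(offsets)) == 1, ]
  if (connectivity == 18) offsets <- offsets[rowSums(abs(offsets)) <= 2, ]
  labels <- array(0L, d)
  lab <- 0L
  todo <- which(binary)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      ijk <- c(rem %% d[1], rem %/% d[1], k) + 1L
      for (o in seq_len(nrow(offsets))) {
        nb <- ijk + offsets[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (binary[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# AUC via the rank-sum (Mann-Whitney U) statistic, ties counted one half.
auc_rank_oracle <- function(pos, neg) {
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Compact two-group cohort design used by recovery-style tests.
small_two_group_design <- function(n_a = 11L, n_b = 13L, rng_seed = 1L,
                                   n_volumes = 240L) {
  cohort_design(group_sizes = c(SUC = n_a, CON = n_b),
                n_volumes = n_volumes, rng_seed = rng_seed)
}

# fALFF branch preprocessing for one simulated subject record.
process_falff <- function(rec, brain, fwhm_mm = 4) {
  b <- discard_initial_volumes(rec$bold, 10)
  b <- smooth_gaussian(b, fwhm_mm)
  b <- detrend_linear(b, brain)
  normalize_global_mean(amplitude_map(b, brain, kind = "fALFF"))
}

# Connectivity branch preprocessing for one simulated subject record.
process_fc <- function(rec, masks) {
  b <- discard_initial_volumes(rec$bold, 10)
  b <- bandpass_filter(b, band_spec())
  mo <- motion_trace(rec$motion$translations[-(1:10), , drop = FALSE],
                     rec$motion$rotations[-(1:10), , drop = FALSE])
  nu <- suppressWarnings(build_nuisance(mo, b, masks$rois$csf, masks$rois$wm,
                                        include_global = TRUE,
                                        global_mask = masks$brain))
  b <- regress_nuisance(b, nu)
  fc_zmap(b, seed_timecourse(b, masks$rois$ba17), masks$brain,
          seed_label = "ba17")
}
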