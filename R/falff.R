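#' One-sided amplitude spectrum of a time series
#'
#' Fast Fourier Transform of the series followed by the square root of the
#' per-bin power.  Amplitudes use the RMS convention: a unit-amplitude
#' sinusoid at an exact bin yields amplitude 1/sqrt(2) at that bin, and
#' Parseval's identity holds as `sum(amplitude^2) == mean(ts^2)`.
#'
#' @param ts Numeric time series, length >= 8.
#' @param tr_s Sampling interval in seconds.
#' @return An object of class `freq_spectrum`: list with `freqs_hz`
#'   (DFT bin centers from 0) and `amplitude` (sqrt of power per bin).
#' @export
amplitude_spectrum <- function(ts, tr_s) {
  n <- length(ts)
  if (n < 8L) abort("Series too short: need at least 8 time points.")
  if (tr_s <= 0) abort("`tr_s` must be positive.")
  # every non-DC bin carries the doubled one-sided power; the Nyquist bin of
  # even-length series is treated like any interior bin so that band ratios
  # are uniform in |X| (Parseval is then exact for odd-length series)
  X <- fft(ts)
  half <- n %/% 2
  k <- 0:half
  scale <- rep(sqrt(2) / n, half + 1L)
  scale[1] <- 1 / n
  structure(list(freqs_hz = k / (n * tr_s),
                 amplitude = Mod(X[k + 1L]) * scale,
                 tr_s = tr_s, n = n),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("<freq_spectrum> %d bins, 0-%.4g Hz (spacing %.4g Hz)\n",
              length(x$freqs_hz), max(x$freqs_hz), x$freqs_hz[2]))
  invisible(x)
}

band_bin_index <- function(freqs_hz, band) {
  which(freqs_hz >= band$low_hz - 1e-12 & freqs_hz <= band$high_hz + 1e-12)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Mean of the amplitude spectrum (square root of power) across the bins
#' inside the band, inclusive of both edges.
#'
#' @param ts Numeric time series.
#' @param tr_s Sampling interval in seconds.
#' @param band A [band_spec()] (default 0.01-0.08 Hz).
#' @return Nonnegative scalar.
#' @export
alff <- function(ts, tr_s, band = band_spec()) {
  sp <- amplitude_spectrum(ts, tr_s)
  idx <- band_bin_index(sp$freqs_hz, band)
  if (!length(idx))
    abort(sprintf("No DFT bin inside [%.4g, %.4g] Hz; bin spacing is %.4g Hz.",
                  band$low_hz, band$high_hz, sp$freqs_hz[2]))
  mean(sp$amplitude[idx])
}

#' Fractional ALFF (fALFF)
#'
#' Ratio of the summed square-root power inside the band to the summed
#' square-root power over the entire frequency range.  The DC bin is excluded
#' from both sums, so the value is scale-invariant and lies in [0, 1].
#' An all-zero series yields 0 with a warning rather than an error, so cohort
#' runs survive degenerate voxels.
#'
#' @inheritParams alff
#' @return Scalar in [0, 1].
#' @export
falff <- function(ts, tr_s, band = band_spec()) {
  sp <- amplitude_spectrum(ts, tr_s)
  amp <- sp$amplitude[-1]           # DC excluded from both sums
  total <- sum(amp)
  if (total == 0) {
    warn("All-zero series: fALFF defined as 0.")
    return(0)
  }
  idx <- band_bin_index(sp$freqs_hz[-1], band)
  sum(amp[idx]) / total
}

#' Voxelwise ALFF / fALFF map
#'
#' Applies [alff()] or [falff()] to every in-mask voxel of a preprocessed
#' series (provenance must show that volume discarding and detrending have
#' been applied).  Out-of-mask voxels are 0.  Degenerate (zero-spectrum)
#' voxels get value 0 and are listed in the map's QC log.
#'
#' @param series A preprocessed [bold_series()].
#' @param mask A [brain_mask()] on the same grid.
#' @param band A [band_spec()].
#' @param kind `"fALFF"` (default) or `"ALFF"`.
#' @return An `amplitude_map`: 3D data grid plus `kind`, `normalized`
#'   (FALSE), `band`, `mask` and a `qc` tibble of flagged voxels.
#' @export
amplitude_map <- function(series, mask, band = band_spec(),
                          kind = c("fALFF", "ALFF")) {
  kind <- match.arg(kind)
  require_provenance(series, c("discard", "detrend"))
  if (!same_grid(series, mask)) abort("Series and mask grids differ.")
  nt <- dim(series$data)[4]
  half <- nt %/% 2
  idx <- as.vector(mask$data)
  tmat <- series_matrix(series)[, idx, drop = FALSE]
  A <- Mod(mvfft(tmat))[1:(half + 1L), , drop = FALSE]
  scale <- rep(sqrt(2) / nt, half + 1L)
  scale[1] <- 1 / nt
  A <- A * scale
  freqs <- (0:half) / (nt * series$tr_s)
  bidx <- band_bin_index(freqs, band)
  if (!length(bidx))
    abort(sprintf("No DFT bin inside [%.4g, %.4g] Hz; bin spacing is %.4g Hz.",
                  band$low_hz, band$high_hz, freqs[2]))
  if (kind == "ALFF") {
    vals <- colMeans(A[bidx, , drop = FALSE])
    degenerate <- colSums(A[-1, , drop = FALSE]) == 0
  } else {
    total <- colSums(A[-1, , drop = FALSE])
    inband <- colSums(A[bidx, , drop = FALSE])
    degenerate <- total == 0
    vals <- ifelse(degenerate, 0, inband / ifelse(total == 0, 1, total))
  }
  data <- array(0, dim3_of(mask))
  data[mask$data] <- vals
  qc <- NULL
  if (any(degenerate)) {
    ijk <- which(mask$data, arr.ind = TRUE)[degenerate, , drop = FALSE]
    qc <- tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                         reason = "zero-spectrum voxel")
  }
  new_amplitude_map(data, kind = kind, normalized = FALSE, band = band,
                    mask = mask, qc = qc)
}

#' Normalize an amplitude map by its global (within-mask) mean
#'
#' @param map An unnormalized `amplitude_map` with positive in-mask mean.
#' @return The map with each in-mask voxel divided by the in-mask mean and
#'   `normalized = TRUE`.
#' @export
normalize_global_mean <- function(map) {
  if (isTRUE(map$normalized)) abort("Map is already normalized.")
  m <- mean(map$data[map$mask$data])
  if (m <= 0) abort("In-mask mean is not positive; cannot normalize.")
  map$data[map$mask$data] <- map$data[map$mask$data] / m
  map$normalized <- TRUE
  map
}
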