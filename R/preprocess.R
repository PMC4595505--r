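#' Discard initial volumes of a BOLD run
#'
#' Drops the first `n_discard` volumes (signal-equilibration frames) and
#' records the step in the series provenance.
#'
#' @param series A [bold_series()].
#' @param n_discard Number of leading volumes to drop (default 10).
#' @return The shortened [bold_series()].
#' @export
discard_initial_volumes <- function(series, n_discard = 10L) {
  nt <- dim(series$data)[4]
  if (n_discard < 0) abort("`n_discard` must be nonnegative.")
  if (n_discard >= nt)
    abort(sprintf("Cannot discard %d of %d volumes.", n_discard, nt))
  if (n_discard > 0)
    series$data <- series$data[, , , (n_discard + 1L):nt, drop = FALSE]
  add_provenance(series, "discard")
}

#' Framewise displacement of a motion trace
#'
#' Per-frame head-motion summary: the sum of absolute backward differences of
#' the three translations plus `head_radius_mm` times the sum of absolute
#' rotation differences (radians projected onto a sphere of that radius).
#' The first frame is 0 by convention; the mean is taken over frames 2..t.
#'
#' @param motion A [motion_trace()].
#' @param head_radius_mm Sphere radius for the rotational arc length
#'   (default 50 mm).
#' @return List with `fd` (length-t numeric, mm) and `mean_fd` (mm).
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  t <- nrow(motion$translations)
  if (t < 2L) abort("Framewise displacement needs at least 2 time points.")
  dtr <- abs(diff(motion$translations))
  dro <- abs(diff(motion$rotations))
  fd <- c(0, rowSums(dtr) + head_radius_mm * rowSums(dro))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Check a motion trace against exclusion limits
#'
#' Flags a subject for exclusion when the maximum absolute cumulative
#' translation on any axis exceeds `trans_limit_mm` or the maximum absolute
#' cumulative rotation on any axis exceeds `rot_limit_deg` (rotations are
#' stored in radians and converted here).
#'
#' @param motion A [motion_trace()].
#' @param trans_limit_mm Translation limit in mm (default 2.0).
#' @param rot_limit_deg Rotation limit in degrees (default 2.0).
#' @return List with `exclude` (logical), `max_trans_mm`, `max_rot_deg`, and
#'   the offending axes.
#' @export
exceeds_motion_limits <- function(motion, trans_limit_mm = 2.0,
                                  rot_limit_deg = 2.0) {
  if (trans_limit_mm < 0 || rot_limit_deg < 0)
    abort("Motion limits must be nonnegative.")
  mt <- apply(abs(motion$translations), 2, max)
  mr <- apply(abs(motion$rotations), 2, max) * 180 / pi
  list(exclude = max(mt) > trans_limit_mm || max(mr) > rot_limit_deg,
       max_trans_mm = max(mt), trans_axis = which.max(mt),
       max_rot_deg = max(mr), rot_axis = which.max(mr))
}

#' Remove the per-voxel linear trend
#'
#' Least-squares removal of intercept + slope x time from every in-mask
#' voxel series; out-of-mask voxels are untouched.
#'
#' @param series A [bold_series()].
#' @param mask A [brain_mask()] on the same grid.
#' @return The detrended [bold_series()].
#' @export
detrend_linear <- function(series, mask) {
  if (!same_grid(series, mask)) abort("Series and mask grids differ.")
  if (!any(mask$data)) abort("Mask is empty.")
  nt <- dim(series$data)[4]
  idx <- as.vector(mask$data)
  Y <- series_matrix(series)[, idx, drop = FALSE]
  X <- cbind(1, seq_len(nt))
  beta <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% beta
  v <- matrix(series$data, prod(dim3_of(series)), nt)
  v[idx, ] <- t(resid)
  series$data <- array(v, dim(series$data))
  add_provenance(series, "detrend")
}

# Per-|frequency| gain of the zero-phase band-pass: 1 inside the band,
# cosine taper of width `transition_hz` outside each edge, 0 at DC.
bandpass_gain <- function(f, band, transition_hz) {
  g <- numeric(length(f))
  inb <- f >= band$low_hz - 1e-12 & f <= band$high_hz + 1e-12
  g[inb] <- 1
  lo <- f > band$low_hz - transition_hz & f < band$low_hz
  g[lo] <- 0.5 * (1 + cos(pi * (band$low_hz - f[lo]) / transition_hz))
  hi <- f > band$high_hz & f < band$high_hz + transition_hz
  g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band$high_hz) / transition_hz))
  g[f == 0] <- 0
  g
}

#' Zero-phase band-pass filter
#'
#' Phase-insensitive filtering by masking the DFT of each voxel series: unit
#' gain at every bin inside the band, a cosine roll-off of width
#' `transition_hz` outside the edges, zero gain at DC and in the far
#' stopband.  Because only bin magnitudes are altered, no phase shift is
#' introduced.
#'
#' @param series A [bold_series()].
#' @param band A [band_spec()]; its upper edge must not exceed the series
#'   Nyquist frequency.
#' @param transition_hz Width of the cosine roll-off (default 0.005 Hz).
#' @return The filtered [bold_series()].
#' @export
bandpass_filter <- function(series, band, transition_hz = 0.005) {
  check_band_nyquist(band, series$tr_s)
  nt <- dim(series$data)[4]
  f <- (seq_len(nt) - 1) / (nt * series$tr_s)
  f <- pmin(f, 1 / series$tr_s - f)  # |frequency| of each DFT bin
  g <- bandpass_gain(f, band, transition_hz)
  Y <- mvfft(series_matrix(series))
  filt <- Re(mvfft(Y * g, inverse = TRUE)) / nt
  series$data <- array(t(filt), dim(series$data))
  add_provenance(series, "bandpass")
}

gaussian_axis_matrix <- function(n, sigma_vox) {
  radius <- max(1L, ceiling(3.5 * sigma_vox))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- abs(a - b)
    ifelse(d <= radius, exp(-d^2 / (2 * sigma_vox^2)), 0)
  })
  K / rowSums(K)  # boundary-renormalized: constants are preserved exactly
}

smooth_volume <- function(vol, sigmas) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigmas[ax] <= 0) next
    K <- gaussian_axis_matrix(d[ax], sigmas[ax])
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    v <- array(K %*% matrix(v, d[ax]), d[perm])
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with a kernel of the given full width at
#' half maximum, expressed in mm and converted per axis through the voxel
#' size (sigma = FWHM / 2.3548).  The kernel is normalized so constants are
#' preserved; 4D input is smoothed volume by volume.
#'
#' @param x A [bold_series()], [brain_mask()]-shaped 3D array wrapped in an
#'   `amplitude_map`, or plain 3D array.
#' @param fwhm_mm Full width at half maximum in mm (> 0).
#' @param voxel_size_mm Voxel sizes, required only for plain arrays.
#' @return The same type as `x`, smoothed.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 4, voxel_size_mm = NULL) {
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0) abort("`fwhm_mm` must be positive.")
  vs <- if (!is.null(voxel_size_mm)) voxel_size_mm
        else if (is.list(x) && !is.null(x$affine)) voxel_sizes(x$affine)
        else if (is.list(x) && !is.null(x$mask)) voxel_sizes(x$mask$affine)
        else abort("Provide `voxel_size_mm` for plain arrays.")
  sigmas <- fwhm_mm / (2.3548 * vs)
  if (inherits(x, "bold_series")) {
    nt <- dim(x$data)[4]
    for (tt in seq_len(nt))
      x$data[, , , tt] <- smooth_volume(x$data[, , , tt], sigmas)
    return(add_provenance(x, "smooth"))
  }
  if (inherits(x, "amplitude_map")) {
    x$data <- smooth_volume(x$data, sigmas)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(smooth_volume(x, sigmas))
  if (is.array(x) && length(dim(x)) == 4L) {
    for (tt in seq_len(dim(x)[4])) x[, , , tt] <- smooth_volume(x[, , , tt], sigmas)
    return(x)
  }
  abort("Unsupported input type for smoothing.")
}
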