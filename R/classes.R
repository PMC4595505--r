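#' Construct a 4D BOLD series
#'
#' The basic container for one subject's resting-state run: a 4D array
#' (x, y, z, time) of BOLD signal in arbitrary scanner units, a voxel-to-world
#' affine in mm, the repetition time, and a provenance trail recording which
#' temporal operations have been applied (used to enforce pipeline order).
#'
#' @param data 4D numeric array, dimensions (x, y, z, t) with t >= 2.
#' @param tr_s Repetition time in seconds (> 0).
#' @param affine 4x4 voxel-to-world transform (mm). Defaults to
#'   `diag(c(voxel_size_mm, 1))`.
#' @param voxel_size_mm Length-3 voxel edge lengths in mm, used only when
#'   `affine` is missing.
#' @param provenance Character vector of operations already applied.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr_s, affine = NULL, voxel_size_mm = c(3, 3, 3),
                        provenance = character()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    abort("`data` must be a 4D array (x, y, z, t).")
  if (dim(data)[4] < 2L) abort("A BOLD series needs at least 2 time points.")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    abort("`tr_s` must be a single positive number.")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  check_affine(affine)
  structure(
    list(data = data, affine = affine, tr_s = as.numeric(tr_s),
         provenance = as.character(provenance)),
    class = "bold_series"
  )
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    abort("`affine` must be a 4x4 matrix.")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    abort("`affine` must be invertible.")
  invisible(affine)
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %dx%dx%d grid, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat("  voxel size (mm):", paste(signif(voxel_sizes(x$affine), 4), collapse = " x "), "\n")
  cat("  provenance:", if (length(x$provenance)) paste(x$provenance, collapse = " -> ")
      else "(raw)", "\n")
  invisible(x)
}

#' Construct a binary brain or ROI mask
#'
#' @param data 3D array of 0/1 (or logical) values with at least one nonzero
#'   voxel.
#' @param affine 4x4 voxel-to-world transform; defaults to
#'   `diag(c(voxel_size_mm, 1))`.
#' @param voxel_size_mm Voxel edge lengths used when `affine` is missing.
#' @return An object of class `brain_mask` whose `data` is a logical 3D array.
#' @export
brain_mask <- function(data, affine = NULL, voxel_size_mm = c(3, 3, 3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("A mask must be a 3D array.")
  vals <- unique(as.vector(data[!is.na(data)]))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    abort(paste0("Mask values must be 0/1; offending values: ",
                 paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", ")))
  ldat <- array(as.logical(data), dim(data))
  if (!any(ldat)) abort("Mask has no nonzero voxel.")
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  check_affine(affine)
  structure(list(data = ldat, affine = affine), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %dx%dx%d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Construct a head-motion trace
#'
#' Rigid-body realignment parameters in the SPM `rp_*.txt` convention:
#' three translations in mm and three rotations in radians per time point.
#'
#' @param translations t x 3 numeric matrix (mm).
#' @param rotations t x 3 numeric matrix (radians).
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    abort("Translations and rotations must each have 3 columns.")
  if (nrow(translations) != nrow(rotations))
    abort("Translations and rotations must have the same number of rows.")
  structure(list(translations = translations, rotations = rotations),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d time points; max |trans| %.3g mm, max |rot| %.3g deg\n",
              nrow(x$translations), max(abs(x$translations)),
              max(abs(x$rotations)) * 180 / pi))
  invisible(x)
}

#' Specify a temporal frequency band
#'
#' @param low_hz Lower band edge in Hz (default 0.01).
#' @param high_hz Upper band edge in Hz (default 0.08).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz = 0.01, high_hz = 0.08) {
  if (!(low_hz > 0 && high_hz > low_hz))
    abort("Need 0 < low_hz < high_hz.")
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "band_spec")
}

check_band_nyquist <- function(band, tr_s) {
  nyq <- 1 / (2 * tr_s)
  if (band$high_hz > nyq + 1e-12)
    abort(sprintf("Band upper edge %.4g Hz exceeds the Nyquist frequency %.4g Hz.",
                  band$high_hz, nyq))
  invisible(band)
}

new_amplitude_map <- function(data, kind, normalized, band, mask, qc = NULL) {
  structure(list(data = data, kind = kind, normalized = normalized,
                 band = band, mask = mask, qc = qc),
            class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  inmask <- x$data[x$mask$data]
  cat(sprintf("<amplitude_map> kind %s, %s, band %.3g-%.3g Hz\n",
              x$kind, if (x$normalized) "normalized (in-mask mean 1)" else "unnormalized",
              x$band$low_hz, x$band$high_hz))
  cat(sprintf("  in-mask mean %.4g, range [%.4g, %.4g]\n",
              mean(inmask), min(inmask), max(inmask)))
  invisible(x)
}

new_stat_map <- function(stat, p, df, mask, kind) {
  structure(list(stat = stat, p = p, df = df, mask = mask, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  s <- x$stat[x$mask$data]
  cat(sprintf("<stat_map> kind %s, df (%s); in-mask |stat| max %.4g\n",
              x$kind, paste(signif(unlist(x$df), 5), collapse = ", "),
              max(abs(s))))
  invisible(x)
}

# ---- shared helpers ---------------------------------------------------------

voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

voxel_volume_mm3 <- function(affine) prod(voxel_sizes(affine))

#' Convert voxel indices to world coordinates
#'
#' Applies the affine to 1-based voxel indices (i, j, k). Indices are
#' converted to the 0-based convention before the affine is applied, matching
#' NIfTI practice.
#'
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1)
  xyz <- h %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Convert world coordinates back to 1-based voxel indices
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of voxel indices (possibly fractional).
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1)
  ijk <- h %*% t(solve(affine))
  ijk[, 1:3, drop = FALSE] + 1
}

same_grid <- function(a, b) identical(dim3_of(a), dim3_of(b))

dim3_of <- function(x) {
  d <- dim(if (is.list(x)) x$data else x)
  d[1:3]
}

# t x V matrix of the voxel time series selected by a logical 3D index
series_matrix <- function(series, voxels = NULL) {
  d <- dim(series$data)
  v <- matrix(series$data, prod(d[1:3]), d[4])
  if (!is.null(voxels)) v <- v[as.vector(voxels), , drop = FALSE]
  t(v)
}

add_provenance <- function(series, step) {
  series$provenance <- c(series$provenance, step)
  series
}

require_provenance <- function(series, steps) {
  missing <- setdiff(steps, series$provenance)
  if (length(missing))
    abort(paste0("Series has not been through required preprocessing step(s): ",
                 paste(missing, collapse = ", ")))
  invisible(series)
}
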