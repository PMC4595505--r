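#' Describe a ground-truth effect region for the synthetic cohort
#'
#' A region is a set of grid voxels plus, per group, a multiplier on the
#' amplitude of the in-band (0.01-0.08 Hz by default) fluctuation and a
#' coupling coefficient in [-1, 1] describing how strongly (and with which
#' sign) the region's in-band fluctuation is shared with the designated seed
#' region's common component.
#'
#' @param region_id Character label.
#' @param voxels n x 3 integer matrix of 1-based grid coordinates.
#' @param inband_gain Named numeric vector (group -> gain); groups not listed
#'   default to 1. A single unnamed value applies to all groups.
#' @param coupling_to_seed Named numeric vector (group -> coupling in [-1, 1]);
#'   groups not listed default to 0. A single unnamed value applies to all.
#' @return An object of class `region_effect`.
#' @export
region_effect <- function(region_id, voxels, inband_gain = 1,
                          coupling_to_seed = 0) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (nrow(voxels) == 0L) abort("`voxels` must be nonempty.")
  if (any(inband_gain < 0)) abort("`inband_gain` must be nonnegative.")
  if (any(abs(coupling_to_seed) > 1)) abort("`coupling_to_seed` must lie in [-1, 1].")
  structure(list(region_id = as.character(region_id), voxels = voxels,
                 inband_gain = inband_gain, coupling_to_seed = coupling_to_seed),
            class = "region_effect")
}

lookup_group_value <- function(map, group, default) {
  if (is.null(names(map))) {
    if (length(map) == 1L) return(unname(map))
    abort("Per-group values must be named by group.")
  }
  if (group %in% names(map)) unname(map[[group]]) else default
}

block_voxels <- function(xr, yr, zr) {
  as.matrix(expand.grid(x = xr, y = yr, z = zr))
}

#' Default ground-truth region layout for the phantom cohort
#'
#' Three effect regions on a 16^3 grid: a "BA17-like" occipital seed block
#' (60 voxels) with elevated in-band amplitude in the seizure-uncontrolled
#' (SUC) and drug-resistant (DR) groups, a near-seed block positively coupled
#' to the seed (most strongly in SUC), and a distal DMN-like block negatively
#' coupled to the seed (most strongly in SUC).  Two small neutral blocks act
#' as CSF- and WM-like nuisance-signal compartments.
#'
#' @param groups Group labels used to key the per-group effects.
#' @return List of [region_effect()] objects.
#' @export
default_region_specs <- function(groups = c("SUC", "SC", "DR", "WH", "CON")) {
  g <- function(...) {
    v <- c(...)
    stats::setNames(v, groups[seq_along(v)])
  }
  list(
    region_effect("ba17", block_voxels(6:10, 3:6, 7:9),
                  inband_gain = g(2, 1, 2, 1, 1),
                  coupling_to_seed = 0.7),
    region_effect("occ_near", block_voxels(6:10, 8:10, 7:9),
                  inband_gain = 1,
                  coupling_to_seed = g(0.6, 0.25, 0.4, 0.25, 0.25)),
    region_effect("dmn_distal", block_voxels(6:10, 12:14, 7:9),
                  inband_gain = 1,
                  coupling_to_seed = g(-0.45, -0.1, -0.3, -0.1, -0.1)),
    region_effect("csf", block_voxels(3:4, 3:4, 3:4), inband_gain = 0),
    region_effect("wm", block_voxels(13:14, 3:4, 3:4), inband_gain = 0)
  )
}

#' Design a synthetic multi-group resting-state cohort
#'
#' Fixes every parameter of the phantom cohort: acquisition grid and timing,
#' group sizes, ground-truth effect regions, and noise/drift/motion levels.
#' The full cohort is a pure function of the design (and in particular of
#' `rng_seed`).
#'
#' @param grid_shape Length-3 integer vector of voxels per axis (each >= 4).
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Volumes per run.
#' @param group_sizes Named integer vector, group label -> number of subjects.
#' @param region_specs List of [region_effect()] objects with pairwise
#'   disjoint voxel sets inside the grid.
#' @param seed_region Label of the region whose common component defines the
#'   couplings.
#' @param band [band_spec()] of the synthesized in-band fluctuation.
#' @param baseline Mean signal level (arbitrary units).
#' @param band_amplitude SD of the unit-gain in-band fluctuation.
#' @param noise_sd SD of the additive white Gaussian noise.
#' @param drift_slope_sd SD across voxels of the linear drift slope
#'   (signal units per volume).
#' @param motion_sd_mm,motion_sd_deg Per-step SDs of the bounded random-walk
#'   motion trace.
#' @param motion_bound_mm,motion_bound_deg Clamp bounds of the walk.
#' @param rng_seed Integer master seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(grid_shape = c(16L, 16L, 16L),
                          voxel_size_mm = c(3, 3, 3),
                          tr_s = 2.0,
                          n_volumes = 240L,
                          group_sizes = c(SUC = 11L, SC = 10L, DR = 8L,
                                          WH = 11L, CON = 13L),
                          region_specs = default_region_specs(names(group_sizes)),
                          seed_region = "ba17",
                          band = band_spec(0.01, 0.08),
                          baseline = 100,
                          band_amplitude = 0.75,
                          noise_sd = 2,
                          drift_slope_sd = 0.01,
                          motion_sd_mm = 0.05,
                          motion_sd_deg = 0.05,
                          motion_bound_mm = 1.5,
                          motion_bound_deg = 1.5,
                          rng_seed = 1L) {
  if (any(grid_shape < 4L)) abort("All grid dimensions must be >= 4.")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    abort("`group_sizes` must be a named vector.")
  if (any(group_sizes < 1L)) abort("All group sizes must be >= 1.")
  if (n_volumes < 2L) abort("`n_volumes` must be >= 2.")
  check_band_nyquist(band, tr_s)
  design <- structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm, tr_s = tr_s,
         n_volumes = as.integer(n_volumes),
         group_sizes = group_sizes, region_specs = region_specs,
         seed_region = seed_region, band = band, baseline = baseline,
         band_amplitude = band_amplitude, noise_sd = noise_sd,
         drift_slope_sd = drift_slope_sd,
         motion_sd_mm = motion_sd_mm, motion_sd_deg = motion_sd_deg,
         motion_bound_mm = motion_bound_mm, motion_bound_deg = motion_bound_deg,
         rng_seed = as.integer(rng_seed),
         affine = diag(c(voxel_size_mm, 1))),
    class = "cohort_design")
  validate_regions(design)
  design
}

validate_regions <- function(design) {
  seen <- integer(0)
  for (reg in design$region_specs) {
    v <- reg$voxels
    inside <- v >= 1L & sweep(v, 2, design$grid_shape, "<=")
    if (!all(inside))
      abort(sprintf("Region '%s' has voxels outside the %s grid.",
                    reg$region_id, paste(design$grid_shape, collapse = "x")))
    lin <- (v[, 3] - 1L) * prod(design$grid_shape[1:2]) +
      (v[, 2] - 1L) * design$grid_shape[1] + v[, 1]
    if (any(lin %in% seen))
      abort(sprintf("Region '%s' overlaps a previously declared region.",
                    reg$region_id))
    seen <- c(seen, lin)
  }
  invisible(design)
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %s grid, %d volumes @ TR %.3g s, %d subjects in %d groups\n",
              paste(x$grid_shape, collapse = "x"), x$n_volumes,
              sum(x$group_sizes), length(x$group_sizes)))
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat("  regions:", paste(vapply(x$region_specs, `[[`, "", "region_id"),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Build the phantom brain mask and per-region ROI masks
#'
#' The brain mask is the grid interior (a one-voxel shell is left outside),
#' covering every declared region plus the surrounding bulk.  Each region gets
#' a binary ROI mask on the same grid; all masks carry the design's affine.
#'
#' @param design A [cohort_design()].
#' @return List with elements `brain` (a [brain_mask()]) and `rois` (named
#'   list of [brain_mask()] objects, one per region).
#' @export
build_phantom_masks <- function(design) {
  validate_regions(design)
  d <- design$grid_shape
  bulk <- array(FALSE, d)
  bulk[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  rois <- list()
  for (reg in design$region_specs) {
    m <- array(FALSE, d)
    m[reg$voxels] <- TRUE
    bulk <- bulk | m
    rois[[reg$region_id]] <- brain_mask(m, affine = design$affine)
  }
  list(brain = brain_mask(bulk, affine = design$affine), rois = rois)
}

# Unit-SD band-limited series: equal-amplitude sinusoids with independent
# uniform phases at every exact DFT bin inside the band.
band_component_matrix <- function(n, tr_s, band, n_series) {
  k <- seq_len(n %/% 2)
  fk <- k / (n * tr_s)
  kb <- k[fk >= band$low_hz - 1e-12 & fk <= band$high_hz + 1e-12]
  if (!length(kb))
    abort("No DFT bin falls inside the band; series too short for this band.")
  ph <- matrix(runif(length(kb) * n_series, 0, 2 * pi), length(kb), n_series)
  X <- matrix(0 + 0i, n, n_series)
  X[kb + 1L, ] <- (n / 2) * exp(1i * ph)
  X[n + 1L - kb, ] <- Conj(X[kb + 1L, , drop = FALSE])
  ts <- Re(mvfft(X, inverse = TRUE)) / n
  ts / sqrt(length(kb) / 2)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one subject's BOLD run and motion trace
#'
#' Every voxel's series is baseline + linear drift + white Gaussian noise +
#' a band-limited fluctuation synthesized from exact DFT-bin sinusoids, whose
#' amplitude is scaled by the voxel's region gain for the subject's group.
#' Voxels of regions with nonzero coupling share a common band-limited
#' component with the seed region, with the specified sign and strength.
#' Identical (design, group, subject_seed) triples reproduce bit-identical
#' output.
#'
#' @param design A [cohort_design()].
#' @param group Group label, must be one of `names(design$group_sizes)`.
#' @param subject_seed Integer seed for this subject.
#' @return An object of class `subject_record`: list with `subject_id`
#'   (filled by [simulate_cohort()]), `group`, `bold` ([bold_series()]),
#'   `motion` ([motion_trace()]) and `truth` (per-region gain/coupling used).
#' @export
simulate_subject_bold <- function(design, group, subject_seed) {
  if (!group %in% names(design$group_sizes))
    abort(sprintf("Unknown group label '%s'.", group))
  d <- design$grid_shape
  n <- design$n_volumes
  V <- prod(d)
  with_seed(subject_seed, {
    seed_common <- band_component_matrix(n, design$tr_s, design$band, 1L)[, 1]
    indep <- band_component_matrix(n, design$tr_s, design$band, V)
    gain <- rep(1, V)
    coupling <- rep(0, V)
    truth <- list()
    for (reg in design$region_specs) {
      lin <- (reg$voxels[, 3] - 1L) * prod(d[1:2]) +
        (reg$voxels[, 2] - 1L) * d[1] + reg$voxels[, 1]
      g <- lookup_group_value(reg$inband_gain, group, 1)
      cc <- lookup_group_value(reg$coupling_to_seed, group, 0)
      gain[lin] <- g
      coupling[lin] <- cc
      truth[[reg$region_id]] <- list(inband_gain = g, coupling_to_seed = cc)
    }
    coupled <- which(coupling != 0)
    if (length(coupled)) {
      cc <- coupling[coupled]
      indep[, coupled] <- outer(seed_common, cc) +
        sweep(indep[, coupled, drop = FALSE], 2, sqrt(1 - cc^2), "*")
    }
    amp <- design$band_amplitude * gain
    slopes <- rnorm(V, 0, design$drift_slope_sd)
    mat <- sweep(indep, 2, amp, "*") +
      outer(seq_len(n) - 1, slopes) +
      matrix(rnorm(n * V, 0, design$noise_sd), n, V) +
      design$baseline
    bold <- bold_series(array(t(mat), c(d, n)), tr_s = design$tr_s,
                        affine = design$affine)
    walk <- function(sd, bound) {
      w <- apply(matrix(rnorm(3L * n, 0, sd), n, 3L), 2, cumsum)
      pmin(pmax(w, -bound), bound)
    }
    motion <- motion_trace(
      translations = walk(design$motion_sd_mm, design$motion_bound_mm),
      rotations = walk(design$motion_sd_deg, design$motion_bound_deg) * pi / 180
    )
    structure(list(subject_id = NA_character_, group = group, bold = bold,
                   motion = motion, truth = truth,
                   subject_seed = as.integer(subject_seed)),
              class = "subject_record")
  })
}

#' Simulate a full multi-group cohort
#'
#' Generates `sum(design$group_sizes)` subjects with per-subject seeds derived
#' deterministically from `design$rng_seed`, plus the phantom masks and a
#' group-assignment table.  When `out_dir` is given, writes one 4D NIfTI per
#' subject, one SPM-dialect `rp_<id>.txt` motion file per subject, the masks,
#' a `cohort.tsv` group table, and a `truth.json` ground-truth sidecar.
#'
#' @param design A [cohort_design()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `records` (list of subject records), `masks`
#'   (see [build_phantom_masks()]), `group_table` (tibble with subject_id,
#'   group, bold_path, motion_path) and `design`.
#' @export
simulate_cohort <- function(design, out_dir = NULL) {
  masks <- build_phantom_masks(design)
  groups <- rep(names(design$group_sizes), design$group_sizes)
  ids <- unlist(lapply(names(design$group_sizes), function(g)
    sprintf("%s%02d", g, seq_len(design$group_sizes[[g]]))))
  seeds <- (design$rng_seed + seq_along(ids) * 9973L) %% 2147483647L
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- simulate_subject_bold(design, groups[i], seeds[i])
    rec$subject_id <- ids[i]
    records[[i]] <- rec
  }
  bold_path <- rep(NA_character_, length(ids))
  motion_path <- rep(NA_character_, length(ids))
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok || file.access(out_dir, 2) != 0)
      abort(sprintf("Output directory '%s' is not writable.", out_dir))
    for (i in seq_along(records)) {
      bold_path[i] <- file.path(out_dir, paste0(ids[i], ".nii"))
      motion_path[i] <- file.path(out_dir, paste0("rp_", ids[i], ".txt"))
      write_bold(records[[i]]$bold, bold_path[i])
      write_motion(records[[i]]$motion, motion_path[i])
    }
    write_mask(masks$brain, file.path(out_dir, "brain_mask.nii"))
    for (rid in names(masks$rois))
      write_mask(masks$rois[[rid]], file.path(out_dir, paste0("roi_", rid, ".nii")))
    truth <- lapply(records, function(r)
      list(subject_id = r$subject_id, group = r$group,
           subject_seed = r$subject_seed, regions = r$truth))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  group_table <- tibble::tibble(subject_id = ids, group = groups,
                                bold_path = bold_path,
                                motion_path = motion_path)
  if (!is.null(out_dir))
    utils::write.table(group_table, file.path(out_dir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = records, masks = masks, group_table = group_table,
       design = design)
}
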