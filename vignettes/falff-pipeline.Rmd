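---
title: "Methods: fALFF, cluster-extent inference and seed connectivity in falffpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fALFF, cluster-extent inference and seed connectivity in falffpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

falffpipe implements a resting-state BOLD analysis built around two
statistics of spontaneous low-frequency brain activity:

1. the **fractional amplitude of low-frequency fluctuations (fALFF)** of
   every voxel's time series, used as a regional biomarker (for example of
   primary-visual-cortex hyperactivity), and
2. **seed-based functional connectivity**, the Fisher-z-transformed Pearson
   correlation between a seed region's mean time course and every brain
   voxel.

Group inference on both is voxelwise (one-way ANOVA, pooled-variance
two-sample t, one-sample t) with multiple-comparisons control by
**Monte-Carlo cluster-extent correction** in the AlphaSim tradition, and
the ROI-level biomarker claim is quantified with **ROC analysis** (AUC,
Hanley–McNeil confidence interval, Youden cut-point).

The pipeline assumes its inputs are already spatially aligned to a common
grid: it performs no slice-timing, realignment or spatial normalization.
Real-data users must supply pre-aligned 4D NIfTI volumes, a binary brain
mask, per-subject rigid-body motion traces (SPM `rp_*.txt` dialect:
three translations in mm, three rotations in radians), and ROI masks on the
same grid.

## The temporal pipeline and its order

Two branches share the initial steps but then deliberately diverge:

* **fALFF branch**: discard initial volumes → spatial Gaussian smoothing →
  linear detrend → fALFF → global-mean normalization.
* **Connectivity branch**: discard initial volumes → zero-phase band-pass
  (0.01–0.08 Hz) → nuisance regression → seed correlation → Fisher z.

The band-pass is intentionally *absent* from the fALFF branch. fALFF is the
ratio of in-band square-root power to square-root power over the whole
frequency range; if the series were band-passed first, the denominator
would collapse onto the numerator and the ratio would degenerate to ≈ 1 at
every voxel, destroying the statistic's self-normalizing construction. The
band specification (default 0.01–0.08 Hz) instead defines the numerator
range. In the connectivity branch the filter genuinely removes
high-frequency physiological noise and low-frequency drift before
correlation, and precedes nuisance regression, so that the regressors are
removed from exactly the signal that enters the correlation.

`amplitude_map()` enforces this by provenance: it requires that volume
discarding and detrending have been applied; `fc_zmap()` requires band-pass
and nuisance regression. Each `bold_series` carries its ordered provenance
trail.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tr_s` | 2.0 | s | Typical EPI repetition time; configuration wins over NIfTI headers (headers are unreliable), mismatches > 1% log a warning. |
| `n_discard` | 10 | volumes | Signal equilibration and subject adaptation. |
| band | 0.01–0.08 | Hz | The canonical low-frequency fluctuation band; both edges inclusive with a 1e-12 Hz tolerance so exact DFT bins are never lost to float rounding. |
| `fwhm_mm` | 4 | mm | Spatial smoothing full width at half maximum; σ = FWHM/2.3548, converted per axis by voxel size. |
| motion limits | 2.0 / 2.0 | mm / degrees | Subject exclusion on maximum absolute cumulative translation/rotation. Published practice varies between 2.0 and 2.5 in otherwise identical protocols; both are honest choices and the limit is a plain config parameter. |
| FD head radius | 50 | mm | Sphere radius projecting rotation increments to arc length in the framewise-displacement summary. |
| `voxel_p` | 0.05 | – | Two-sided voxel-level cluster-forming threshold. |
| `alpha` | 0.05 | – | Family-wise corrected level for cluster survival. |
| `n_iterations` | 1000 | – | Monte-Carlo iterations of the cluster null. |
| `connectivity` | 26 | – | Cluster neighbourhood (6/18/26); the data thresholding and the null always share one setting. |
| `include_global` | TRUE | – | Global-signal regression in the nuisance set; contested in the field, hence switchable, and both paths are tested. |

## Spectral conventions

The one-sided amplitude spectrum uses an RMS convention: amplitudes are
`sqrt(2)|X_k|/n` for every bin above DC and `|X_0|/n` at DC. Two details
are deliberate:

* **The DC bin is excluded** from both the fALFF numerator and denominator.
  Detrended signals carry no meaningful DC, and including it would make the
  ratio depend on numerical detrend residue. "The entire frequency range"
  is therefore read as (0, Nyquist].
* **The Nyquist bin of even-length series is scaled like any interior
  bin.** This keeps every band ratio identical to the ratio of raw DFT
  magnitudes — the natural reference for a direct-summation cross-check —
  at the cost of making the one-sided Parseval identity exact only for
  odd-length series. For band statistics the uniform ratio is the property
  that matters.
* **No window function** is applied before the FFT; spectral leakage from
  non-bin frequencies is accepted and documented as a limitation.

All-zero voxel series (possible at mask edges) yield fALFF 0 and are
recorded in the map's QC table rather than raising, so cohort runs survive
degenerate voxels.

## The Monte-Carlo cluster null

Each iteration fills the grid with independent standard Gaussian noise,
smooths it to the stated FWHM, re-standardizes within the mask, thresholds
two-sidedly at the voxel p threshold, and records the maximal cluster size,
clustering positive and negative voxels **separately** — exactly what the
data path does, since a map can contain adjacent increase and decrease
clusters that must not merge. The minimum surviving size is

    k_min(alpha) = (the ceil((1 - alpha) * n_iterations)-th order statistic
                    of the per-iteration maxima) + 1,

and survival requires `size > k_min` (strict). This construction controls
the family-wise error of observing any supra-threshold cluster of the
surviving size or larger; the calibration tests show the realized rate on
null cohorts is near, and bounded by, nominal.

The null's smoothness defaults to the smoothing FWHM actually applied to
the maps (4 mm for the fALFF branch, 0 for the unsmoothed connectivity
z-maps). When comparing against cluster thresholds printed in published
studies, note that those depend on the *estimated* smoothness of the actual
data — a quantity rarely reported — so printed `k_min` values are generally
not recoverable from the settings alone; an explicit FWHM override exists
for that reason.

If the requested FWHM is under 0.1 voxel on every axis, the null proceeds
unsmoothed with a warning rather than failing.

## ROC conventions

* Positive calls use **strict inequality** (score > cut). With continuous
  fALFF values ties are measure-zero, but the convention is fixed for
  reproducibility.
* The cut-point is the **Youden maximizer** (sensitivity + specificity − 1),
  ties broken toward the lower threshold.
* The AUC confidence interval is the normal approximation with the
  **Hanley–McNeil** standard error and is **not clipped** to [0, 1],
  matching the SPSS-era reporting convention in which upper bounds slightly
  above 1 appear in print. The p value against AUC = 0.5 uses the same
  standard error.
* Pairwise group t-tests on the ROI scalar are reported **raw**, without
  multiplicity adjustment, mirroring how such tables are conventionally
  reported; users wanting adjustment can apply `p.adjust` to the output.

## Connectivity sign maps and the change taxonomy

Correlations are clamped to |r| ≤ 1 − 1e−7 before `atanh`, so the seed's
own voxels stay finite and remain in the map. Per-group signs
(positive / negative / none) come from cluster-corrected one-sample t-tests
on the Fisher-z maps. Between-group changes are labeled by
`classify_change()`:

* shared sign → *increased*/*decreased* of that sign, where "increased"
  means larger **magnitude** in the first group (more positive z for
  positive connectivity, more negative z for negative connectivity) — the
  only reading consistent with describing strengthened anticorrelation as
  "negative connectivity increased";
* differing signs (including one `none`) → `positive_change` or
  `negative_change`, the direction of the group difference in z units.

## The synthetic cohort generator

`cohort_design()` fixes the study conditions: a five-group cohort
(SUC 11, SC 10, DR 8, WH 11, CON 13 — 53 subjects), 240 volumes at
TR 2 s on a 3 mm grid, with

* a 60-voxel "BA17-like" occipital block whose in-band amplitude gain is 2
  in the SUC and DR groups and 1 elsewhere,
* a near-seed block positively coupled to the seed (0.6 in SUC, 0.4 in DR,
  0.25 otherwise),
* a distal DMN-like block negatively coupled (−0.45 in SUC, −0.3 in DR,
  −0.1 otherwise),
* two small neutral blocks acting as CSF- and WM-like nuisance
  compartments.

Voxel series are baseline + linear drift + white Gaussian noise + a
band-limited component synthesized from equal-amplitude sinusoids at every
exact DFT bin inside 0.01–0.08 Hz with independent uniform phases, so the
generated in-band energy is leakage-free and analytically accountable.
Coupled voxels share a per-subject common band component with the seed
region at the specified correlation. The default grid is 16³ — large enough
for cluster geometry and a surrounding bulk, small enough that a full
53-subject cohort simulates in seconds.

Amplitude and noise defaults (band component SD 0.75, noise SD 2.0,
baseline 100, drift slope SD 0.01 per volume) were calibrated once, before
any acceptance measurement, so that the voxelwise amplitude effect is
subtle (single-voxel Cohen's d ≈ 3 before smoothing; nothing survives
without the cluster machinery at small samples in the coupling-only
regions) while the 60-voxel ROI mean remains strongly discriminative — the
regime in which both the cluster correction and the ROC biomarker are
meaningfully exercised. With these values the normalized ROI-mean fALFF sits
near 1.1–1.5, the same range as published region-level values.

Motion traces are bounded random walks (per-step SD 0.05 mm / 0.05°,
clamped at ±1.5 mm/°). They exist to exercise the framewise-displacement
computation and the exclusion logic, not to model physiology.

What the generator does **not** emulate: hemodynamic response shape,
scanner artifacts and spatial noise correlation (noise is iid across
voxels; spatial smoothness enters only through the explicit smoothing
step), physiological (cardiac/respiratory) structure, slice-timing effects,
or realistic head-motion spectra. Passing recovery tests therefore
demonstrate that the *computational machinery* is correct and calibrated
under its own assumptions — not that effect sizes of this magnitude are
realistic in patient data.

## Numerical choices

* **Band-pass**: zero-phase DFT masking — unit gain at in-band bins, cosine
  roll-off of width 0.005 Hz outside each edge, zero at DC. Because only
  magnitudes are altered, no phase shift is introduced; the contract is
  gain within 5% of unity in-band and below 0.05 at DC and at twice the
  upper edge.
* **Smoothing**: separable Gaussian via per-axis banded matrices, kernel
  truncated at 3.5σ, rows renormalized at the boundary so constants are
  preserved exactly and interior impulses keep unit mass.
* **Detrend**: exact least-squares intercept + slope removal per voxel,
  solved once for all in-mask voxels via the normal equations.
* **Cluster labeling**: depth-first search in C++ (6/18/26 neighbourhood);
  deterministic ordering by size (descending), then lexicographic peak
  coordinate; peaks maximize |stat| with first-index tie-breaks.
* **Degenerate cells**: zero pooled variance in a t-test gives t = 0,
  p = 1 with a QC record; identical-in-all-subjects ANOVA voxels give
  F = 0, p = 1; zero-variance voxels in connectivity get r = 0 with a QC
  record.
* **Determinism**: the whole cohort is a pure function of the design;
  per-subject seeds derive from the design seed; Monte-Carlo nulls take an
  explicit seed and the RNG state is restored afterwards.

## Problem sizes used by the test suite

The suite validates on deliberately desk-scale problems: the 16³ default
phantom, a 20³ grid with 200 replicate null cohorts for the family-wise
error calibration (the calibration operates at the amplitude-map level —
per-subject maps are smoothed standardized Gaussian fields, which is the
exact object the group-inference and correction stages consume, so it tests
the correction machinery directly), 1000-iteration cluster nulls, and ten
cohort replicates for the amplitude- and connectivity-recovery checks.
These sizes give binomial confidence intervals tight enough to detect a
miscalibrated correction while keeping a full run in minutes.

## Known limitations

* No spatial preprocessing (alignment, normalization) — by design.
* No window before the FFT; short series with strong off-bin components
  leak.
* The Monte-Carlo null models smoothness with the applied smoothing FWHM,
  not an estimate from residuals; real data with intrinsic smoothness
  beyond the applied kernel need the FWHM override.
* The pooled-variance t assumes equal group variances; a Welch option is
  not provided because the downstream cluster machinery is calibrated for
  the pooled form.
* ROC confidence intervals are large-sample normal approximations; at
  n ≈ 10 per group they are indicative, not exact.
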