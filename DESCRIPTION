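Package: falffpipe
Title: Resting-State fMRI fALFF and Seed-Based Connectivity Analysis with
    Monte Carlo Cluster-Extent Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for resting-state BOLD fMRI analysis:
    temporal preprocessing (volume discarding, framewise-displacement motion QC,
    linear detrending, zero-phase band-pass filtering, Gaussian smoothing),
    voxelwise (fractional) amplitude of low-frequency fluctuations (ALFF/fALFF),
    group inference with Monte Carlo cluster-extent multiple-comparisons
    correction, ROI-based ROC biomarker evaluation, and seed-based functional
    connectivity with Fisher r-to-z transformation and a connectivity-change
    taxonomy.  Includes a deterministic multi-group synthetic BOLD cohort
    generator with known ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
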