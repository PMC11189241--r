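Package: lonesense
Title: Multi-Device Digital Phenotyping Pipeline for Momentary Loneliness Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a fully objective pipeline for detecting momentary
    loneliness from passively sensed smart-device data. Includes a synthetic
    multi-device cohort generator with known ground truth (latent loneliness
    process coupled to physiological and behavioral streams), a wrist PPG
    processing chain (signal quality assessment, short-gap reconstruction,
    systolic peak detection, HR/HRV features per 12-minute segment),
    behavioral feature extraction from phone event logs and GPS traces
    (home and place detection, mobility, communication, notification and
    screen features), EMA-aligned dataset assembly with per-feature window
    optimisation, missing-data filtering and imputation, per-participant
    median-split labels and z-normalization, per-participant temporal-holdout
    random-forest detection with pooled metrics and per-device ablation, and
    path-dependent TreeSHAP feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    ranger,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
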