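Package: jaeknee
Title: Joint Acoustic Emission Analysis for Knee Arthritis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible vibroarthrography pipeline for classifying
    juvenile idiopathic arthritis (JIA) from knee joint acoustic emissions
    recorded by two skin-mounted accelerometers during flexion-extension
    cycles. Includes a synthetic cohort generator with class-dependent
    transient click statistics and subject- and leg-level random effects,
    wavelet shrinkage denoising, zero-phase band-pass filtering, overlapping
    200-ms framing, a versioned 273-feature time-frequency catalogue with
    per-knee mean/standard-deviation aggregation, a standardization + PCA +
    gradient-boosted-tree joint-score classifier, leave-one-leg-out
    cross-validation, and ROC/AUC and Kolmogorov-Smirnov evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
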