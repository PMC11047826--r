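Package: dnscreen
Title: Screening Diabetic Neuropathy from Wearable Inertial Sensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening diabetic peripheral
    neuropathy from six-axis inertial recordings of standardized
    neurological movement exercises. Raw accelerometer/gyroscope streams
    are reduced to an orientation-invariant norm signal, gap-filled,
    gravity-filtered and summarized as cumulative Welch spectral band
    powers; small labelled cohorts are expanded by class-conditional
    Gaussian kernel-density synthesis; one classifier per exercise is
    tuned by grid search and the six outputs are averaged into a
    neuropathy probability. Companion statistical analyses (pooled
    t-tests, chi-square contingency tests, masked Pearson correlation
    matrices against nerve-conduction parameters) and a fully
    parameterized synthetic-data generator for both signal-level
    recordings and feature-level cohorts are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    glmnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
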