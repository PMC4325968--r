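Package: seizepipe
Title: Generalised Scalp-EEG Seizure Detection Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A cross-patient (generalised) epileptic seizure detection
    pipeline for multichannel scalp EEG: repair of missing samples,
    Butterworth decomposition into the classical delta/theta/alpha/beta
    bands, per-channel spectral and time-domain feature extraction (RMS,
    variance, skewness, kurtosis, peak and median frequency, signal
    entropy, band energy, correlation dimension), whole-brain and
    region-grouped feature ranking and selection, SMOTE oversampling,
    nine reference classifiers behind one fit/score interface, and a
    repeated-holdout / k-fold evaluation harness reporting sensitivity,
    specificity, ROC/AUC and global error. A seeded synthetic EEG
    generator reproduces the statistical structure the method assumes
    (dominant ictal oscillation, elevated delta/theta energy, reduced
    entropy) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    class,
    rpart,
    e1071,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC
Config/testthat/edition: 3
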