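Package: gaitstate
Title: Medication On/Off State Detection from Knee-Worn Accelerometer Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline analysis pipeline for detecting the dopaminergic
    medication "On"/"Off" state of Parkinson's disease patients from bilateral
    knee-worn tri-axial accelerometer recordings sampled at 32 Hz. Provides
    Butterworth low-pass preprocessing, 320-sample (10 s) fold segmentation,
    windowed statistical and spatiotemporal gait feature extraction (16 named
    features per knee), recursive feature elimination, four classifier families
    (random forest, RBF support vector machine, k-nearest neighbours, Gaussian
    naive Bayes) with published hyperparameter defaults, Gaussian-process
    expected-improvement hyperparameter optimization, subject-level 70:30 and
    leave-one-subject-out evaluation with confusion-matrix bookkeeping
    (sensitivity, specificity, PPV, diagnostic odds ratio, rank-based ROC-AUC
    with bootstrap confidence intervals), and a synthetic bilateral gait-signal
    simulator with ground-truth annotations for end-to-end validation without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    ranger,
    e1071,
    class,
    lhs,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
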