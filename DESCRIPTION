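Package: mwload
Title: Mental Workload Classification from Facial Thermography and Heart
    Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for assessing
    driver mental workload from facial infrared thermography and
    electrocardiography. Provides a synthetic multi-phase cohort generator,
    Hampel artifact rejection and baseline normalisation for thermal
    region-of-interest traces, R-peak detection and time/frequency-domain
    heart-rate-variability features, sample entropy and Welch band-power
    descriptors, subject-grouped k-fold cross-validation of sixteen
    classifier presets across six model families, wrapper feature selection
    over random subsets, and ROC/confusion-matrix evaluation for two-class
    and three-class cognitive-task designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    e1071,
    caret,
    randomForest,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
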