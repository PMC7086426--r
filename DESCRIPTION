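Package: eegtbi
Title: Moderate Traumatic Brain Injury Detection from Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for detecting moderate traumatic brain injury
    (TBI) from resting-state eye-closed electroencephalography (EEG). Converts
    multichannel recordings (European Data Format or plain matrix files) into
    per-second channel-by-sample matrices, defines and trains a fixed nine-layer
    convolutional network on the raw matrices, and evaluates classifiers with
    subject-level threefold cross-validation wrapped in a bootstrap that yields
    mean accuracy, standard deviation and a 95% confidence interval. Four
    conventional feature-engineered comparison pipelines (Gaussian Naive Bayes
    on band power and envelope connectivity, AdaBoost on frontal log-PSD
    features, SVM on MRMR-selected spectral features, and SVM on alpha band
    power) share the same cross-validation contract. A seeded synthetic EEG
    cohort generator with tunable alpha-attenuation and theta-gain class
    effects makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    rpart,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
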