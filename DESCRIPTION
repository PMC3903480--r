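Package: tgdecode
Title: Temporal Generalization Decoding for Epoched Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate pattern analysis for epoched
    multichannel recordings (MEG/EEG). Trains a linear support vector
    machine with Platt probability calibration at every time sample under
    stratified cross-validation, tests each classifier at every other time
    sample, and assembles the resulting train-time by test-time matrix of
    ROC areas (the temporal generalization matrix). Nonparametric
    within-subject (Mann-Whitney) and across-subject (Wilcoxon signed-rank)
    inference with Benjamini-Hochberg false discovery rate control
    distinguishes serial ("diagonal") from sustained ("square") neural
    dynamics, including below-chance (sign-reversed) generalization. A
    generative simulator of sequential, sustained and polarity-reversing
    sensor-level generators, and of local-global oddball session label
    sequences, reproduces both dynamical regimes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
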