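Package: prostEM
Title: Stacked-Ensemble Malignancy Scoring and Staging for Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Auxiliary decision support for prostate cancer built on six routine
    tumor markers (PSA, PSMA, tPSA, RBC, HB, PAP). A soft-margin support vector
    machine gates benign from malignant cases; a stacked ensemble of three
    one-vs-one SVM committees with perturbed kernels, three multilayer
    perceptrons, and three radial-basis-function networks feeds an exponential
    linear regression that maps the concatenated base-learner outputs to a
    continuous evaluation-of-malignancy (EM) score. The log score (lnEM) drives
    clinical staging (I-IV), treatment recommendation, and treatment-effect
    tracking. A seeded synthetic cohort generator with an exponential
    marker-growth law stands in for hospital records and supports calibration,
    learning-curve, and covariate analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
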