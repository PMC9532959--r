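Package: ckdhmm
Title: Continuous-Time Hidden Markov Models for Kidney Function Stage Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits continuous-time hidden Markov models for the progression of
    chronic kidney disease through eGFR stages (G1/2, G3a, G3b, G4, G5) with an
    absorbing death state, allowing neighbour-constrained misclassification of
    the observed stage. Transition intensities are uni-directional and scale
    multiplicatively with covariates (sex, heart failure, cancer, optional
    hypertension and diabetes) and annually updated age. Provides forward-algorithm
    likelihood evaluation with exactly observed death times, maximum-likelihood
    fitting with Wald confidence intervals, Viterbi decoding with under-/over-grading
    summaries, monitoring-policy metrics (progression, true- and false-positive
    detection probabilities at fixed horizons), split-sample calibration of
    predicted stage occupancy, and a synthetic panel-cohort generator emulating
    irregular primary-care eGFR testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
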