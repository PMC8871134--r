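Package: gwjoint
Title: Bayesian Joint Modeling of Gestational Weight Gain and Infant Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits a hierarchical Bayesian joint model linking sparse,
    irregularly sampled longitudinal gestational weight measurements to
    infant birth weight. Maternal weight trajectories are modeled as
    subject-specific piecewise-linear (linear spline) curves whose
    parameters, together with the log within-subject residual variance,
    enter the birth-weight regression as random-effect predictors.
    Estimation is by Gibbs sampling with an inverse-CDF step for the
    non-conjugate residual-variance conditionals and an empirical-Bayes
    Wishart prior on the random-effect covariance. The package also
    implements the two-stage linear-regression comparator based on
    precomputed interval-specific weight-gain rates, a synthetic cohort
    generator emulating a pregnancy cohort with mixed self-reported and
    clinical weight measurements, convergence diagnostics, and reporting
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
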