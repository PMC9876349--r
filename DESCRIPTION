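Package: spheroidadapt
Title: Tumour Spheroid Growth and Oxygen-Adaptation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic modelling of avascular tumour spheroid growth under
    constant and time-dependent external oxygen availability. Implements
    closed-form steady-state oxygen and metabolic-waste profiles inside a
    spherically symmetric spheroid, the Greenspan growth model with its
    algebraic structure constraints, and extensions describing adaptation to
    instantaneous deoxygenation and re-oxygenation through exponentially
    relaxing model parameters. Includes per-spheroid snapshot estimators of
    the critical necrotic radius, oxygen consumption rate, and inhibition
    thresholds, a synthetic radial-measurement generator emulating end-point
    spheroid experiments, and a calibration workflow built on multistart
    maximum likelihood, profile-likelihood identifiability analysis, and
    adaptive-Metropolis Bayesian inference with Gelman-Rubin diagnostics and
    posterior prediction intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
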