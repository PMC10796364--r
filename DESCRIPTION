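Package: nitjm
Title: Neurological Intervention Transition Joint Models for Dynamic
    Prognosis in Subarachnoid Haemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint models of longitudinal intensive-care measurements and
    time to good clinical outcome after spontaneous subarachnoid
    haemorrhage, with a patient-specific change point at the time of
    neurological intervention (aneurysm clipping or embolisation).
    Provides piecewise linear mixed-effects trajectory sub-models, Cox
    screening of baseline covariates, a shared-parameter Bayesian joint
    model estimated by adaptive Metropolis-Hastings-within-Gibbs MCMC,
    dynamic individual risk prediction conditional on survival and the
    accumulated measurement history, time-dependent AUC evaluation grids,
    and a synthetic intensive-care cohort simulator with known generative
    parameters for recovery and discrimination studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
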