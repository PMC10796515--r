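Package: radresp
Title: Predictive Modelling of Tumour Volume Response to Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-compartment (living/necrotic) tumour volume model with
    impulsive radiotherapy dosing to gross tumour volume (GTV) time series.
    Per-patient posteriors are sampled with a robust adaptive Metropolis
    algorithm under independent log-uniform priors, pooled into a
    population-level posterior, and expanded with truncated Silverman kernels
    into a second-level prior used by a bootstrap particle filter to make
    real-time, uncertainty-quantified predictions and treatment-response
    classifications for new patients. Includes a synthetic-cohort generator
    emulating weekly CT measurements with volume-dependent Gaussian noise, so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
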