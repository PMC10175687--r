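Package: teicopk
Title: Population Pharmacokinetics and Dosing Simulation of Teicoplanin in Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis and dosing-regimen
    optimization of teicoplanin in critically ill septic adults. Implements the
    analytic two-compartment intravenous-infusion model with multi-dose
    superposition, a log-normal inter-individual variability layer with a
    renal-function (GFR) power covariate on clearance and proportional residual
    error, a Laplace-approximation nonlinear mixed-effects estimator with
    likelihood-ratio covariate selection, bootstrap and prediction-corrected
    visual predictive check diagnostics, a synthetic sparse-sampling cohort
    generator, and Monte Carlo simulation of loading/maintenance regimens with
    trough, AUC/MIC, probability of target attainment (PTA) and cumulative
    fraction of response (CFR) evaluation against MRSA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
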