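Package: mtxppk
Title: Population Pharmacokinetics of High-Dose Methotrexate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Population pharmacokinetic modelling of high-dose methotrexate
    given as a split intravenous infusion. Provides analytic one-, two- and
    three-compartment infusion kinetics, a covariate model on clearance and
    central volume (eGFR, body weight, bleomycin co-medication, total
    bilirubin, albumin), first-order conditional (FOCE/Laplace) nonlinear
    mixed-effects estimation, stepwise covariate selection by
    likelihood-ratio thresholds, bootstrap, visual predictive check and
    normalized prediction distribution error diagnostics, and a
    synthetic-cohort generator emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
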