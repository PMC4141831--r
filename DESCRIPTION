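Package: warfpkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of Warfarin
    Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequential population pharmacokinetic-pharmacodynamic analysis
    of warfarin induction therapy: a one-compartment model for plasma
    S-warfarin, an indirect-response (turnover) model for normal prothrombin
    (NPT), and a nonlinear NPT-to-INR link, estimated by first-order
    conditional (Laplace) approximate marginal likelihood with log-normal
    inter-individual variability. Includes a synthetic-cohort generator
    emulating a 99-patient Asian initiation trial (covariate distributions,
    CYP2C9/VKORC1/CYP4F2 genotype frequencies, loading-dose protocols,
    sparse sampling), stepwise covariate selection by objective-function
    value, non-parametric bootstrap confidence intervals, goodness-of-fit
    diagnostics, and the cohort-level statistics used to study
    over-anticoagulation (INR >= 4): allele frequencies, odds ratios,
    rank tests, and stepwise logistic regression with c-statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pracma,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
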