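Package: pridedose
Title: Intra-Patient Dose Escalation Designs with Patient Random Effects for
    Phase I Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decision machinery for phase I dose-finding trials
    in small populations where enrolled patients may be retreated at
    additional dose levels across treatment cycles. Implements the PRIDE
    (patient retreat in dose escalation) and PRIDE-FA (flexible allocation)
    schemes: a Bayesian hierarchical logistic toxicity model with
    patient-level random effects fitted by Metropolis-Hastings-within-Gibbs
    sampling, calibration-free odds (CFO), BOIN and CRM decision engines, a
    retreatment scheduler with washout-based cohort priority, a discrete-event
    trial simulator, fixed and random toxicity scenario generators, and
    operating-characteristic metrics (MTD selection and allocation, overdose
    rates, sample-size reduction, trial duration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
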