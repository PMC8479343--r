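Package: statswitch
Title: JAK-STAT Apoptosis Switch Dynamics, Drug Scheduling and Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a dimensionless kinetic model of the JAK2/IFN-beta driven
    STAT1-STAT3-Bcl-2-BAX apoptosis switch coupled to logistic tumour growth and
    two drug inputs (interferon-beta and cisplatin). Provides equilibrium and
    saddle-node bifurcation analysis of the intracellular subsystem including
    bistability windows and hysteresis sweeps, a pulsed infusion-schedule engine
    for enumerating and scoring injection orderings, and a forward-backward sweep
    solver for Pontryagin-type optimal dosing problems with quadratic control
    costs. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
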