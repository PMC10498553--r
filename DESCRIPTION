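Package: perspecta
Title: Multi-Perspective Cost-Effectiveness Analysis with Individual-Level
    Microsimulation
Version: 0.1.0
Authors@R:
    person("Joss", "Carver", email = "joss.carver@example.org",
           role = c("aut", "cre"))
Description: Toolkit for cost-effectiveness analyses that compare the health
    sector and patient perspectives. Provides a seeded individual-level
    state-transition Monte Carlo engine with monthly cycles, half-cycle
    corrected discounting, DALY accounting, and dual-perspective cost
    accrual; PERT-based probabilistic sensitivity analysis; efficiency
    frontier, ICER and cost-effectiveness acceptability curve analytics;
    annuity-based affordability assessment; and a five-pattern congruence
    framework for reconciling perspectives. Ships a fully parameterized
    case study of six antiretroviral delivery strategies for HIV treatment
    in Mozambique.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
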