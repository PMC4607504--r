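Package: kinetigrate
Title: Kinetic Models of Central Carbon Metabolism Closed by Genome-Scale
    Steady-State Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses ordinary-differential-equation kinetic models
    of bacterial central carbon metabolism that are closed at their boundaries
    by steady-state fluxes computed from a genome-scale stoichiometric model.
    Provides flux balance and flux variability analysis on stoichiometric
    networks, strain-specific reparameterization against measured exchange
    rates, quadratic-programming projection of carbon-13 flux estimates onto
    the feasible flux space, computation of connecting-reaction closure
    constants, determination of maximal rates and missing steady-state
    metabolite concentrations with minimal parameter adjustment, eigenvalue
    stabilization of a reference steady state, and multistart phase-space
    scanning to enumerate and classify coexisting metabolic steady states.
    Synthetic-data generators produce toy stoichiometric networks with
    enumerable optima, a kinetic motif with known bistability, and
    ground-truth multi-omics tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
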