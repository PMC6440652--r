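Package: circuitOED
Title: Optimal Experimental Design for Synthetic Gene-Circuit ODE Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, sensitivity analysis and Fisher-information based
    optimal experimental design (OED) for two benchmark synthetic gene
    circuits (a direct SKN7m-driven GFP reporter and a phosphotransfer
    buffered variant) induced by doxorubicin.  Provides forward sensitivity
    equations with closed-form Jacobians, Fisher information matrices with
    A-, D-, E- and modified-E optimality criteria and Cramer-Rao lower
    bounds, a harmony-search optimizer (plus genetic-algorithm and particle
    swarm baselines), a two-stage nested design loop that selects the
    optimal induction level while estimating kinetic parameters, and a
    sample-size selection rule trading estimation accuracy against
    measurement cost.  Results are returned as tibbles or as result objects
    with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
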