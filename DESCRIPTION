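Package: dopsr
Title: Budgeted Hybrid Particle Swarm and Dynamically Dimensioned Search
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derivative-free global optimization under a hard function
    evaluation budget, aimed at parameter estimation for biochemical
    kinetic models. Implements DOPS (dynamic optimization with particle
    swarms): a velocity-free multi-swarm particle swarm phase with random
    regrouping that adaptively switches, on stagnation of the global best,
    to a greedy dynamically dimensioned search refinement. Includes the
    multi-switch variant, single-strategy baselines (multi-swarm particle
    swarm only, dynamically dimensioned search only), standard analytic
    test functions (Ackley, Rastrigin, Eggholder, Styblinski-Tang), a
    multi-trial experiment harness with convergence-curve aggregation, and
    a mass-action ordinary differential equation demonstration problem
    with a synthetic time-series data generator and sum-of-squared-error
    objective for parameter-recovery studies.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
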