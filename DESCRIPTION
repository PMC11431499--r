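Package: neurotherm
Title: Stochastic and Information Thermodynamics for Neural Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for the stochastic thermodynamics of
    neural systems. Provides a discrete-state master-equation engine with full
    entropy and information accounting (entropy production and flow,
    Kullback-Leibler divergence, mutual information), one-dimensional Langevin
    simulation with gridded Fokker-Planck thermodynamics, closed-form
    thermodynamics of a Brownian particle in gravity, information-flow
    bookkeeping for bipartite Markov systems (a Maxwell-demon ledger), a noisy
    linear recurrent network inferring a stochastic stimulus velocity,
    stochastic BCM synaptic plasticity with bistable collective weights,
    Kramers escape times and a two-state memory reduction, and a
    pair-approximation solver for chains of interacting multi-state synapses.
    Every closed-form result is exposed so that it can serve as a test oracle
    for the corresponding simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
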