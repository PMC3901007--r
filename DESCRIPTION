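Package: partsim
Title: Declarative Part-Based Model Language and Reference Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A declarative, line-oriented language for describing dynamical
    models of neural and cellular systems as "parts" -- named equation sets
    that compose by inheritance (is-a) and inclusion (has-a, under dotted
    prefixes) -- together with a reference simulator and an ensemble runner.
    Connection parts couple populations of part instances; structural
    dynamics (type transitions) let instances split, differentiate, or die
    at run time, so developmental processes such as dendritic arborization
    and stem-cell lineages can be expressed as equations. Simulation uses
    fixed-step Euler or classical Runge-Kutta integration, vectorized over
    instances, with seeded, fully repeatable random streams. Parameter
    sweeps over any model constant (step grids, Monte Carlo, Latin
    hypercube) run as provenance-tracked ensembles. Packaged examples
    include a three-compartment Hodgkin-Huxley cable, an 80/20
    excitatory-inhibitory spiking network with activity-regime
    classification, and branching-process models of growth-cone dynamics
    and adult neurogenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
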