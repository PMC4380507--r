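Package: kirdyn
Title: Tri-Compartment Neuron-Astrocyte Potassium Dynamics with Kir4.1 Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates activity-dependent potassium cycling between a neuron, an
    astrocyte and the shared extracellular space. A Hodgkin-Huxley neuron with
    concentration-dependent Nernst potentials is driven by a three-state
    facilitation-depression synapse; the astrocyte clears extracellular potassium
    through an inward-rectifier (Kir4.1) conductance and Na/K pumps, with
    volume-weighted mass-conservation equations for potassium and sodium in all
    three compartments. Includes the standard stimulation protocols (single,
    tetanic, repetitive, stochastic sub-firing), a resting-state plus
    single-stimulation anchor calibration, fixed-step fourth-order Runge-Kutta
    integration, and analysis tools for transient kinetics, exponential decay
    fits, potassium redistribution phases, net-uptake phase diagrams and
    time-resolved firing probability over seeded ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    yaml,
    readr
Config/testthat/edition: 3
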