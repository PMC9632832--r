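Package: pmcsim
Title: Periodic Multichannel Stimulation of Plastic Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and theory tools for studying how periodic
    multichannel stimulation (PMCS) reshapes synaptic connectivity in
    networks of excitatory leaky integrate-and-fire neurons with
    spike-timing-dependent plasticity (STDP). Provides a fast
    forward-Euler network simulator with delayed spike delivery and
    event-driven nearest-neighbour STDP, charge-balanced single-pulse and
    burst stimulus waveforms with arbitrary phase-lag delivery patterns
    (including coordinated reset with rapidly varying sequence),
    estimators of stimulus-locked conditional interspike-interval
    densities, and an analytical engine that predicts the mean rate of
    synaptic weight change and the block structure of the synaptic weight
    matrix from those densities. Experiment drivers reproduce standard
    protocols (relaxation to the synchronised state, spiking-response
    statistics, theory-versus-simulation rate comparisons, decoupling and
    motif-induction scenarios) at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
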