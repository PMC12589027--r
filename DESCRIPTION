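Package: snncrit
Title: Noise-Driven Spiking Network Simulation with Criticality and
    Fading-Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for small recurrent spiking
    neural networks driven by escape noise. Implements a conductance-based
    leaky integrate-and-fire network with short-term synaptic depression and
    spike-timing-dependent plasticity (asymmetric excitatory and symmetric
    inhibitory windows), the associated stimulation and spontaneous-activity
    protocols, and three analysis stages: neuronal-avalanche criticality
    (power-law fits and the signed deviation index), excitation-inhibition
    balance from synaptic-current traces, and population decoding of fading
    stimulus memory with sparse multinomial logistic regression. Synthetic
    generators with known ground truth (branching-process avalanche trains,
    labeled evoked responses, correlated current pairs, MEA-like recordings
    with stimulation artifacts) make every analysis stage testable without
    long simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
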