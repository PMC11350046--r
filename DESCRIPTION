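Package: tauhcn
Title: Synaptic Physiology and Ultrastructure Analysis for Tauopathy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for cellular correlates of
    tauopathy-associated HCN channelopathy: extraction of passive membrane
    properties, hyperpolarization-induced voltage sag, rebound and
    conductance-activation (Boltzmann) parameters from patch-clamp traces;
    template-matching detection and kinetic characterization of spontaneous
    excitatory postsynaptic currents; presynaptic ultrastructure
    quantification from vesicle coordinate maps including nearest-neighbor
    clustering statistics; and neuronal morphometry (Sholl profiles, branch
    metrics, spine density and typing) from SWC reconstructions. A
    synthetic-data module generates every input type with controllable
    ground truth - a conductance-based neuron simulator, Poisson synaptic
    event trains, clustered hard-core vesicle point patterns and stochastic
    dendritic trees - so the full pipeline can be exercised and validated
    without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    car
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
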