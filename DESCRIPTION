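Package: cbnsim
Title: Simulation of Variable-Size Purkinje Cell Inputs to Cerebellar Nuclei Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the highly variable sizes of Purkinje cell
    (PC) synapses shape rate and temporal coding in cerebellar nuclei (CbN)
    neurons. Generates PC spike trains with lognormal interspike-interval
    statistics, draws synaptic input populations from a calibrated unitary
    conductance distribution, synthesizes excitatory and inhibitory
    conductance waveforms from biexponential unitary kernels, integrates a
    single-compartment conductance-based integrate-and-fire CbN neuron, and
    provides correlogram, spike-triggered-average, synchrony, pause and
    rate-code analyses together with per-figure experiment drivers.
License: MIT
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
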