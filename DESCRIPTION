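Package: engramsim
Title: Memory-Engram Dynamics in Impaired Excitatory-Inhibitory Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of memory engrams in a conductance-based
    excitatory-inhibitory integrate-and-fire network. Provides the network
    builder with degradation operators (neuron, connection, and weight loss),
    short-term synaptic plasticity, a composite long-term plasticity rule
    (triplet spike-timing-dependent plasticity with heterosynaptic and
    transmitter-induced components), protocols for sequential memory recall,
    duty-cycled rescue stimulation of interneurons, learning of a new engram,
    and bifurcation (hysteresis) analysis of persistent states, together with
    the associated metrics: persistent-state detection, persistence score,
    overlapping proportion, synchrony index, coefficient of variation of
    inter-spike intervals, and oscillation band power. The numerical core is
    compiled clock-driven C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
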