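Package: restdp
Title: Resource-Dependent Heterosynaptic STDP in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent networks of refractory leaky integrate-and-fire
    neurons whose excitatory synapses learn under a resource-dependent
    spike-timing-dependent plasticity (STDP) rule: potentiation draws a limited
    resource from neighboring dendritic spines (heterosynaptic depression with
    exponential distance dependence) or from a per-neuron resource pool, and
    depression relocates synaptic resources back into the pool. Includes the
    stimulation ("learning") and progressive synaptic-degeneration protocols,
    analysis metrics (firing rates, weight statistics, potentiation efficacy,
    spine spacing, delay-weighted graph metrics, survival curves), deterministic
    fixtures, and plain-text serialization of networks, rasters and event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
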