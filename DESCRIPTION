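Package: plastinet
Title: Homeostatic Structural Plasticity in Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of leaky integrate-and-fire networks whose connectivity
    is generated at run time by homeostatic structural plasticity: per-neuron
    synaptic elements grow and shrink along Gaussian growth curves driven by an
    exponentially filtered firing-rate estimate, and are periodically reconciled
    into synapse creation and deletion. Includes runtime steering of the growth
    parameters via timed command schedules, publish/subscribe observation of
    firing rates and connectivity, snapshot save/load of the evolving network,
    builders for a two-population balanced model and a multi-region model with
    a synthetic connectome, and a reference dynamic mean-field integrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
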