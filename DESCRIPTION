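Package: synfirecap
Title: Synfire Chain Embedding and Capacity Analysis in Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and mean-field analysis of synfire chain embedding in
    cortical-scale balanced random networks. Provides a conductance-based (and
    current-based) leaky integrate-and-fire network simulator in which all
    excitatory connections form pool-to-pool synfire links with two-component
    transmission delays, spike-packet and wave extraction from rasters,
    characterization of pulse-packet propagation under Poisson background
    (survival probability, participation probability, pool-to-pool time), a
    self-consistent mean-field solver for firing rates and wave numbers,
    embedding-capacity curves, and a Siegert-formula diffusion analysis
    comparing conductance- and current-based synapse models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
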