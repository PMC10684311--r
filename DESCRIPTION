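Package: achnet
Title: Cholinergic Modulation and Spike-Timing-Dependent Plasticity in
    Two-Module Cortical Network Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates two synaptically coupled excitatory-inhibitory
    lattice networks of Hodgkin-Huxley-type cortical neurons in which
    acetylcholine level is encoded by the maximal conductance of the slow,
    low-threshold M-type potassium current (gKs). Inter-module excitatory
    synapses are plastic under an asymmetric pair-based spike-timing-
    dependent plasticity (STDP) rule; wiring can be random or topographic,
    and gKs/DC drive can be spatially homogeneous or arranged in sigmoidal
    hotspots. Includes analysis tools for population activity traces,
    burst (volley) detection, mean phase coherence between modules, and
    percentage weight-change maps, plus scripted experiment protocols and
    a synthetic spike-volley fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
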