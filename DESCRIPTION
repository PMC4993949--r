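Package: engramosc
Title: Spiking Engram-Oscillator Circuits: Converting Between Spatial and
    Temporal Neural Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates stochastic leaky integrate-and-fire
    excitation-inhibition (E-I) networks in which sparse memory engram
    populations control the frequency and power of a downstream population
    oscillation (spatial-to-temporal conversion), and in which oscillatory
    drive at different frequencies selectively ignites distinct engram
    readout populations (temporal-to-spatial conversion). Provides circuit
    builders for the two motifs, deterministic stimulus generators,
    spike-train analysis (population rates, Welch spectra, activation
    latency, selectivity matrices, spectrum-based decoding), turn-key
    experiment drivers with seed-controlled replication, and a YAML/JSON
    configuration and reporting layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
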