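Package: cinphys
Title: Intrinsic and Synaptic Electrophysiology of Cortical Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for patch-clamp electrophysiology of cortical
    GABAergic interneurons. Extracts intrinsic membrane and action-potential
    features (resting potential, input resistance, rheobase, firing curves,
    spike threshold by third-derivative maximum, half-width, maximal rate of
    rise, fast afterhyperpolarization, spike-frequency accommodation),
    classifies cells as fast-spiking or regular-spiking by a conjunctive
    threshold rule, quantifies spontaneous and evoked inhibitory postsynaptic
    currents (event detection, amplitude, rise time, decay tau, charge,
    paired-pulse ratio, train attenuation), and runs a reduced
    single-compartment conductance-based simulation in which raising the
    Kv3.1 potassium conductance density converts a regular-spiking model
    toward fast-spiking behaviour. A seeded synthetic-data generator produces
    current-clamp cohorts and inhibitory current recordings with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
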