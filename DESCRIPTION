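Package: dbsnet
Title: Spiking-Network Simulation of Deep Brain Stimulation Frequency Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-level spiking-network model of deep brain stimulation
    (DBS) in a thalamo-cortical-output circuit. Simulates four Izhikevich
    neuron populations (thalamocortical relay, excitatory and fast-spiking
    inhibitory cortex, motor output) under clinical-style current pulse
    trains, attributes every spike to the stimulus or to background activity
    with a peristimulus window, and sweeps stimulation frequency to measure
    how endogenous activity is substituted and blocked as frequency rises.
    Includes weight and drive calibration, deterministic seeded simulation,
    raster and frequency-response figures, and CSV/JSON export.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
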