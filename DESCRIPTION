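Package: dentephys
Title: Intracellular Electrophysiology Analysis for the Dentate Mossy-Cell Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for patch-clamp recordings from dentate gyrus
    neurons (mossy cells, granule cells, hilar interneurons). Extracts action
    potential and passive-membrane features (third-derivative voltage
    threshold, rheobase and rheobase charge transfer on ramp protocols,
    waveform kinetics, input resistance), detects spontaneous and miniature
    postsynaptic currents and computes event statistics and
    excitation/inhibition ratios, decomposes stimulation-evoked compound
    postsynaptic currents into underlying EPSC and IPSC by template scaling,
    quantifies XE991-sensitive (Kv7/M-type) currents from voltage-ramp
    subtraction, and analyses theta-gamma stimulation spike probability.
    Includes a synthetic-recording generator with known ground truth so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
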