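Package: pali
Title: Simulation and Analysis of Photoacoustic Lifetime Imaging of Tissue Oxygen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: End-to-end simulator and analysis toolkit for photoacoustic
    lifetime imaging (PALI) of tissue oxygen with methylene blue. Implements
    photon-packet Monte Carlo light transport in voxelized tissue phantoms,
    triplet-state pump-probe photophysics, time-of-flight acoustic projection
    to a focused single-element transducer with noise-equivalent-pressure
    noise modeling, the pump-probe acquisition and correction protocol,
    single/double exponential decay fitting, Stern-Volmer oxygen calibration
    and inversion, imaging-depth evaluation metrics, and design of
    Intralipid/India-ink tissue-mimicking phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
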