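Package: globfit
Title: Global Maximum-Likelihood Fitting for Multi-Channel Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint maximum-likelihood fitting of single-molecule data
    detected in several camera channels (biplane, ratiometric multicolor,
    interferometric 4Pi). Parameters such as 3D position, photon count,
    background and interference phase can be linked (shared) across
    channels, which improves localization precision compared to fitting
    each channel individually. Includes inter-channel transform
    estimation from point sets, multi-channel spline PSF calibration
    from bead z-stacks, candidate detection and ROI extraction,
    Cramer-Rao lower bound computation, ratiometric and
    fixed-photon-ratio color assignment, and a simulator that renders
    Poisson-noise test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
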