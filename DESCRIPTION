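Package: smcproton
Title: Simplified Monte Carlo Dose Kernels for Scanned Proton Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Dose calculation toolkit for proton pencil beam scanning in
    voxelized phantoms. Implements a simplified Monte Carlo (SMC) transport
    engine that tracks individual protons with Highland multiple Coulomb
    scattering kicks and water-equivalent depth accumulation, scoring dose
    from a pristine depth-dose curve in water; a reference analytical pencil
    beam algorithm (PBA) with Fermi-Eyges lateral spread and optional subspot
    decomposition; single-field uniform dose (SFUD) spot-weight optimization;
    and dose-comparison analyses (laterally integrated depth dose, rms
    relative difference, DVH/D95, gamma index). Includes synthetic phantom
    generators, an effective-source beam model with binary PMMA range-shifter
    bookkeeping, and an analytic Bragg-curve generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
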