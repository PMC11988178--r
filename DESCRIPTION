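Package: cxbeam
Title: Convergent X-Ray Beam Teletherapy Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for convergent photon-beam teletherapy.
    Provides the closed-form convergent depth-dose law and photon
    spread-out peak synthesis, relativistic electron tracking through
    voxelized magnetic-field maps, bremsstrahlung target and collimator
    modelling with ASCII phase-space files, turn-integrated beam
    generation, collision-kerma dose deposition on voxel phantoms
    (synthetic water-cube, head and thorax generators included), and
    clinical-style dosimetry metrics: dose-volume histograms, isodose
    volumes, R50 surfaces and focal-spot extension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
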