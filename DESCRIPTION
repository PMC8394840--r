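Package: bnctsim
Title: Cellular Potts Simulation of Alpha-Particle Dose Response in 2D and
    3D Tumor Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lattice-based (cellular Potts) Monte Carlo simulation of boron
    neutron capture therapy at the multicellular scale. Tumor monolayers and
    spheroids are represented as voxel aggregates evolving under
    Metropolis-accepted copy attempts; a subset of cells secretes an
    alpha-particle density field that diffuses and decays on the same lattice,
    and cells die once their cumulative exposure crosses a radioresistance
    threshold. Includes geometry builders for 2D sheets and 3D spheroids,
    a one-time exposure-floor calibration protocol, replicate sweeps over
    dose, threshold and propagation constant, and CSV/VTK/JSON writers for
    downstream analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
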