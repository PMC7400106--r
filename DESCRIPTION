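Package: ppfcAdhesion
Title: Initial Bacterial Adhesion Analysis for Parallel-Plate Flow Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the initial adhesion of bacteria to surfaces
    observed in a parallel-plate flow cell. Provides closed-form
    convective-diffusion transport estimates (Smoluchowski-Levich deposition
    flux, Peclet number, Stokes drag, local Reynolds number), a stochastic
    adhesion/detachment simulator with optional hydrodynamic-shadow blocking
    and a microscopy-like frame renderer, prominence-based cell detection in
    grayscale frames, two-phase linear regression of adhesion kinetics with
    breakpoint selection, and 2D pair-correlation probability-density maps
    with a permutation test for flow-axis blocking anisotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, Spatial, Regression, Software
RoxygenNote: 7.3.3
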