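Package: cryptsem
Title: Subcellular-Element Simulation of Intestinal Crypt Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hybrid stochastic simulator of the small-intestinal crypt.
    Cells are deformable clusters of subcellular elements moving with
    overdamped dynamics on a rigid test-tube basement membrane; Paneth
    cells secrete a diffusible Wnt field solved on a masked regular grid
    and coupled to the cells by cloud-in-cell deposition and trilinear
    sampling; exogenous Wnt and BMP gradients, Notch contact signaling and
    threshold rules drive fate decisions, growth, division and removal.
    Includes scenario definitions for niche-stability experiments
    (local-Wnt production sweeps, BMP and global-Wnt deletion, Paneth
    migration deletion, drag and cycle perturbations, gradient noise),
    ensemble execution, and niche-height, composition and stability
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
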