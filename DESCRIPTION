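Package: turgorcell
Title: Finite-Element Mechanics and Morphometrics of Turgid Plant Cells with
    Edge-Face Wall Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the instantaneous inflation of a meristematic plant cell
    under turgor pressure with a three-dimensional large-deformation
    finite-element solver. The cell wall is a fiber-reinforced hyperelastic
    composite (isotropic matrix, dispersed cellulose-microfibril phase with
    tunable mean orientation and fractional anisotropy, isotropic
    cross-linking term) whose shear moduli can be scaled independently at
    cell edges and faces. Includes scenario sweeps over edge stiffness and
    face anisotropy with displacement and stress-concentration readouts, a
    set of image- and mesh-derived morphometric statistics (nematic-tensor
    texture anisotropy, hysteresis filtering, Manders colocalisation at cell
    edges, root diameter from outline traces, 3D growth decomposition, edge
    intensity enrichment), and seeded synthetic-data generators with ground
    truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
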