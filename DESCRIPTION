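Package: osteoshape
Title: Shape Complexity and Comparative Analysis of 3D Bone Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional shape complexity of bones from
    micro-CT derived point clouds and surface meshes, and relates it to
    life-history traits in a phylogenetic framework. Implements alpha-shape
    complexity profiles anchored at the critical alpha radius (via an
    internal Bowyer-Watson Delaunay tetrahedralization), a bandwidth-
    controlled curvature-energy metric for triangulated surfaces, PCA
    summarisation of multi-scale complexity scores, phylogenetic
    generalized least squares with Pagel's lambda, and nonparametric
    tests of ordinal morphological character scores. Ships a parametric
    generator of baculum-like test geometry with known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    withr,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
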