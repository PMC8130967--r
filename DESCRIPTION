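Package: cytodiffuse
Title: Multiscale Finite-Element Modelling of Diffusive Vesicle Transport
    in Actin-Crowded Cytoplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the actin cytoskeleton obstructs the
    passive (diffusive) transport of finite-size vesicles in a eukaryotic
    cell. Generates stochastic three-dimensional actin-filament networks,
    computes the area fraction of two-dimensional cross-sections that a
    vesicle of given radius cannot access (morphological opening of free
    space), homogenizes the obstructed diffusion problem by solving
    periodic cell problems with linear triangular finite elements to
    obtain effective diffusion tensors, calibrates a two-parameter
    percolation-type power law linking effective diffusivity to the
    inaccessible area fraction, and solves the homogenized time-dependent
    transport problem on a whole-cell domain whose actin density is
    described by a Gaussian mixture model. Includes Monte Carlo
    random-walk validation and a one-dimensional oscillatory-coefficient
    verification problem with analytic solution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
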