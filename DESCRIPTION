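Package: pathscape
Title: Likelihood Landscapes of Phylogenetic Treespace via BHV Geodesics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes phylogenetic likelihood landscapes by sampling
    intermediate trees ("pathtrees") along Billera-Holmes-Vogtmann (BHV)
    geodesics between trees of interest. Implements the geodesic treepath
    (GTP) successive-refinement algorithm for BHV distances and geodesic
    supports, closed-form sampling of trees at arbitrary positions along a
    geodesic, Jukes-Cantor (JC69) log-likelihoods via Felsenstein pruning
    with coordinate-wise branch-length optimization, multidimensional
    scaling of tree distance matrices with convex-hull starting-tree
    extraction, spline interpolation of the likelihood surface, and an
    iterative pipeline that zooms in on high-likelihood regions of
    treespace. Includes a seeded fixture generator (random trees, NNI
    perturbation clouds, JC69 sequence simulation) so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    igraph,
    mgcv,
    ggplot2,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
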