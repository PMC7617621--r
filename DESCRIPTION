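Package: hetwalk
Title: Lattice Random Walks with Inert Spatial Heterogeneities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact generating-function machinery for discrete-time lattice
    random walks perturbed by inert spatial heterogeneities. Builds
    homogeneous nearest-neighbour lazy walks in arbitrary dimension with
    reflecting, periodic or absorbing boundaries, perturbs them with
    probability-conserving defect pairs (permeable barriers, antibarriers,
    one-way gates, long-range connections, sticky and slippery sites), and
    computes occupation probabilities, first-passage, first-return and exit
    statistics via the generalized defect technique: the heterogeneous
    propagator generating function is expressed through a small matrix over
    the defect set, so means and full time-domain distributions follow from
    determinant-free linear solves and numerical inversion of the generating
    function. Includes brute-force oracles (Master-equation iteration, Monte
    Carlo sampling, absorbing-chain linear solves) and scenario builders for
    transdermal drug transport through a brick-and-mortar layer, thigmotaxis
    in a circular arena, and a two-particle coalescence search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
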