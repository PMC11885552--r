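Package: phylomorph
Title: Phylogenetic Geometric Morphometrics and Macroevolutionary Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for macroevolutionary analysis of 2D landmark shape data on
    time-calibrated (generally non-ultrametric) fossil phylogenies: TPS and
    Newick input with strict validation, mirroring and thin-plate-spline
    estimation of missing landmarks, Generalized Procrustes Analysis with
    sliding semilandmarks, phylogenetic ordination (Phylo-PCA and
    phylogenetically aligned component analysis), multivariate phylogenetic
    signal (Kmult with lambda tree scaling), phylogenetic Procrustes
    ANOVA/PGLS with residual-randomization permutation, disparity through
    time with Brownian-motion simulation envelopes, stochastic character
    mapping of binary regimes, multivariate evolutionary model fitting
    (BM, multi-rate BM, OU with one or two optima, early burst) with Akaike
    weights, stepwise forward regime-shift discovery, and parametric-bootstrap
    model adequacy. Includes seeded synthetic-data generators emulating
    fossil trees, regime traits and landmark datasets so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
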