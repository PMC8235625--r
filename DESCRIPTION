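Package: morphorate
Title: Phylogenetically-Informed 3D Geometric Morphometrics and
    Evolutionary Rate-Shift Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for 3D geometric-morphometric analysis of limb
    long bones in a phylogenetic comparative framework: curve resampling,
    template-based surface semilandmark patching onto triangulated meshes,
    bending-energy sliding of semilandmarks, generalized Procrustes
    superimposition and species mean forms; phylogenetic signal (Blomberg's
    K and its multivariate generalization), simulation-based phylogenetic
    ANOVA, MANCOVA on retained principal components; between-group PCA with
    cross-validated typicality classification and permutation tests;
    phylogenetic ridge regression with per-branch evolutionary rates and
    randomization tests for clade rate shifts; composite-tree construction
    by branch-length rescaling and binary-trait ancestral-state
    reconstruction (maximum parsimony and stochastic character mapping).
    Includes a synthetic-data generator (bone-like templates, Brownian
    shape evolution with clade rate multipliers, locomotor-group offsets,
    allometry) so the full pipeline can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
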