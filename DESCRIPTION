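Package: fclmap
Title: Four-Cluster Likelihood Mapping and Decisive Supermatrix Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interrogating single phylogenetic splits in large
    amino-acid supermatrices. Implements quartet maximum likelihood under
    empirical substitution models (LG, WAG, Poisson) with discrete-GAMMA rate
    heterogeneity, Four-cluster Likelihood Mapping (FcLM) with 2D simplex
    output, compilation of decisive multi-gene supermatrices from per-gene
    alignments and presence/absence tables, BLOSUM62-distance screening of
    alignments for misaligned or contaminant sequences, and maximum-parsimony
    ancestral-state (groundplan) reconstruction of categorical characters on a
    fixed tree. Includes seeded simulators for alignments, gene coverage
    patterns, contaminants and categorical characters so that every stage can
    be exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
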