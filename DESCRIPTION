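Package: dssalign
Title: Dynamics Similarity Scoring by Local Alignment of Anisotropic
    Network Model Slow Modes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares the intrinsic dynamics of superposed protein
    structures by locally aligning the slowest modes of their Anisotropic
    Network Models (ANM). For each mode pair, a residue-by-residue cosine
    score matrix is searched for high-scoring gapless segments
    (Smith-Waterman style, without gaps); the top-scoring matches define
    per-residue dynamical similarity profiles and a scalar dynamics
    similarity score (DSS). Includes sequence-guided iterative Kabsch
    superposition with TM-score, sparse ANM Hessian construction with a
    shift-invert Lanczos eigensolver, pairwise DSS matrices with
    hierarchical clustering and Newick export, a mode-count selection
    scan, reference-state 2-D mapping, and a deterministic synthetic
    structure generator (helices, bundles, multimers, heme-bearing
    chains) for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    ape,
    bio3d,
    graphics,
    igraph,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
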