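Package: stochfate
Title: Hybrid Stochastic-Deterministic Simulation of Omics-Tailored Single-Cell Fate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates virtual populations of single cells in which stochastic
    gene expression (telegraph promoter switching and mRNA birth/death, exact
    stochastic simulation) is coupled on a 30-second exchange interval to a
    deterministic mechanistic network of receptor/ERK/AKT signaling, cell-cycle
    progression, intrinsic and extrinsic apoptosis, and DNA-damage/p53 dynamics.
    Per-gene transcription and translation rate constants are tailored from
    gene-level omics tables (copy number, mRNA and protein abundance, half-lives)
    via molecules-per-cell normalization. Includes virtual experiments (mitogens,
    kinase inhibitors, TRAIL, etoposide, transformation scans), and a
    lasso/SVM/ROC pipeline for quantifying the predictability of stochastic
    cell-fate decisions from protein-level features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    e1071,
    lhs,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
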