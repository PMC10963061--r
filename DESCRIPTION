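Package: tcrpair
Title: Predicting TCR-pMHC Binding with Attention Over Contextual Sequence Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling T cell receptor (TCR) binding to
    peptide-MHC complexes from paired CDR3/V/J/epitope/MHC records.
    Provides preprocessing of VDJdb/IEDB-style tables (gene-name
    unification against a packaged reference, CDR3 anchor repair,
    precision-aware deduplication), cross-validation splits for the
    seen/unseen TCR and epitope pairing tasks (TPP1-TPP4) including
    epitope-balanced and edit-distance-restricted folds, constrained
    negative sampling by TCR-epitope shuffling at a per-epitope 1:5
    ratio, per-residue sequence encodings with pluggable embedding
    backends, a three-headed convolution/multi-head-attention neural
    network trained with a masked weighted binary cross-entropy,
    stochastic weight averaging, per-epitope AUROC/AP evaluation with
    Levenshtein stratification, and a synthetic repertoire generator
    with a planted motif binding rule for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
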