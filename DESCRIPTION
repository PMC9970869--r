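Package: sigforge
Title: Mutational Signature Extraction and Attribution for Somatic Variant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mutational signature analysis of somatic single base
    substitutions (SBS) and small insertions/deletions (indels) in cancer
    whole-genome cohorts. Builds SBS96/SBS288/SBS1536 and ID83 mutation
    catalogs from variant calls and a reference sequence, extracts de novo
    signatures by replicated Kullback-Leibler non-negative matrix
    factorization with consensus clustering and stability-based rank
    selection, decomposes de novo signatures into a reference catalog by
    non-negative least squares with signature addition/removal, refits
    per-sample exposures with background-signature rules and minimum-activity
    filtering, and runs a downstream statistical battery (clock-like age
    correlations, covariate associations, genomic-instability correlations,
    transcriptional/replicational strand asymmetry, microhomology-deletion
    and long-insertion feature quantification). A synthetic-cohort module
    generates ground-truth data so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    pracma,
    jsonlite,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Biostrings,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
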