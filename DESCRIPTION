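Package: homeobias
Title: Subgenome Expression Bias Analysis for Allopolyploid Homoeolog Pairs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies subgenome expression bias in allopolyploid RNA-seq
    data. Starting from a gene-by-sample count (or TPM) matrix, a
    gene-to-subgenome map and a homoeolog-pair table, the package computes
    TPM-normalized expression, whole-transcriptome subgenome summaries
    (detected genes, summed-TPM shares, top-N compositions), the per-pair
    log2(A/C) homoeolog bias statistic with threshold classification,
    hierarchical clustering of bias profiles with recursive k-cuts and
    small-cluster filtering, pair-aware hypergeometric term enrichment, and
    eFP-style relative-expression export tables. A negative-binomial
    simulator with recorded ground truth emulates a multi-subregion,
    multi-stage seed dissection design for end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    mclust
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
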