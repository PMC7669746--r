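Package: stagenet
Title: Stage-Wise Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the gene co-expression landscape changes
    across ordered disease phenotypes (e.g. control and tumor progression
    stages) from bulk RNA-seq counts. Provides mutual-information
    co-expression network inference with deterministic equal-frequency
    binning and optional data-processing-inequality pruning, ranked top-N
    network sparsification across cut-offs, intra-/inter-chromosome
    (cis/trans) topology statistics with power-law degree-distribution
    fits, multi-network edge intersection analysis, per-stage differential
    expression with progressive-gene detection, community detection with
    hypergeometric over-representation, and a negative-binomial synthetic
    cohort generator that plants known co-expression modules, chromosomal
    structure and monotone progressive genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
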