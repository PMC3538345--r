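Package: rnaicompendium
Title: Analysis of RNAi Perturbation Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for multi-batch RNAi knockdown expression compendia:
    batch-matched moderated differential expression against in-batch GFP
    controls, signed excess-over-random target-overlap networks,
    attribute-weighted coexpression clustering, phenotype-expression
    correlation with a batch-restricted permutation null, an uncoupling
    analysis relating total transcriptional change to cell-cycle phenotype,
    and per-cell flow-cytometry quantification of unphosphorylated Cdk1
    versus cell size. Includes a synthetic-data generator that emulates the
    statistical structure of such compendia for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    xml2,
    knitr
Config/testthat/edition: 3
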