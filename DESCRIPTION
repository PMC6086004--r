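Package: corepress
Title: Consensus Panels of Co-Regulated Genes from Multi-shRNA Knockdown
    RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies gene panels co-regulated by two transcriptional
    factors from RNA-seq of shRNA knockdown experiments that use two
    independent hairpin clones per factor plus a control. Provides
    median-of-ratios normalization, per-clone repression-efficiency
    estimation with moderated tests and Benjamini-Hochberg correction, a
    three-criterion consensus panel filter with co-repression ranking,
    exclusive and co-activated panel partitions, panel overlap reports,
    gene-set over-representation (hypergeometric with FDR), a
    comparative-Ct calculator for RT-qPCR validation, and a
    negative-binomial simulator with planted truth labels for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, RNASeq, GeneSetEnrichment
RoxygenNote: 7.3.3
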