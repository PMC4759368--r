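Package: dhslink
Title: Differential DNase I Hypersensitivity Analysis with Enhancer-Gene
    Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for comparing DNase I hypersensitive site (DHS) landscapes
    between cell states: depth normalization of maximal tag densities (MaxD),
    replicate-concordant peak sets, exact conditional tests for differential
    accessibility, two- and three-way common/unique partitions, priority-based
    genomic annotation (promoter > exon > intron > distal), TSS aggregation
    profiles, qPCR titration-of-digestion quality control for replica
    selection, enhancer-to-gene assignment within a configurable TSS distance,
    hypergeometric gene-set enrichment of linked genes, and overlay with
    expression ratios.  A fully synthetic fixture generator with known ground
    truth (genome, gene models, hotspots, per-bp tag tracks, qPCR titrations,
    expression matrix, gene sets) makes the whole pipeline testable without
    any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    fgsea,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
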