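Package: medipr
Title: Window-Based MeDIP-seq Differential Methylation and Interval
    Enrichment Analysis
Version: 0.9.0
Authors@R:
    person("Medipr", "Maintainers", email = "medipr@example.org",
           role = c("aut", "cre"))
Description: Tools for window-based analysis of methylated-DNA
    immunoprecipitation sequencing (MeDIP-seq): fragment extension and
    stacked-read filtering, genome-wide window counting and RPKM
    normalisation, an exact negative-binomial two-group test for calling
    differentially methylated regions (DMRs), genomic-context
    classification (repeats, genic structure, CpG island shores and
    shelves), overlap-enrichment analysis against reference region sets
    with a Monte-Carlo random-region null and exact binomial testing,
    scaled-region meta-profiles with chromosome-matched shuffled
    baselines, and a hard-filter cascade for whole-genome-sequencing
    variant tables.  A synthetic-data generator with known ground truth
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
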