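Package: delscan
Title: Population-Scale Deletion Variability from Dual-Caller Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for characterising deletion structural variants across
    resequenced populations. Per-sample deletion calls from two independent
    structural-variant callers are intersected by reciprocal overlap, size
    filtered, and clustered across samples into deletion loci with
    per-population allele frequencies. Loci are classified by genomic effect
    (coding exon, intronic, regulatory flank, intergenic) against a GFF3 gene
    annotation, tabulated per sample and population by allelic state, and the
    allele-frequency-filtered gene catalog is tested for gene-set enrichment
    with a hypergeometric test and Benjamini-Hochberg adjustment. A companion
    module anchors genetic-map markers to an assembly by ranking tabular
    alignment hits. A fully seeded synthetic-data generator emulates two
    callers with distinct sensitivity, breakpoint jitter and false-positive
    profiles over planted truth deletions, so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
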