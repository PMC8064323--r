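Package: chipislands
Title: Island-Based Differential H3K4me3 ChIP-Seq Analysis for Degraded
    Postmortem Brain Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for H3K4me3 differential epigenomics in
    postmortem brain tissue where RNA degradation precludes transcriptome
    profiling. Implements SICER-style enrichment island calling from
    extended-fragment tags with a Poisson background model and
    Benjamini-Hochberg island FDR, library normalization by random
    downsampling to the smallest sample, cross-sample merged-region
    construction with group Venn partitioning, strand-aware genomic feature
    annotation, fold-change plus Welch-t differential promoter/gene-body
    activity calls, TSS/metagene/region profile matrices with k-means
    clustering, position-weight-matrix motif-frequency scanning of flanked
    intervals, and ChIP-qPCR fold-enrichment statistics with ANOVA and
    Bonferroni post-hoc tests across postmortem intervals. A synthetic-data
    generator with machine-readable ground truth plants promoter enrichment,
    group fold changes, motif occurrences, and postmortem signal decay so
    that every stage is testable end to end.
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
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
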