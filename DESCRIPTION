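Package: pancore
Title: Pan-Genome Core-Gene Classification and Regulatory Genomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reference-guided pan-genome analysis toolkit for hexaploid
    wheat and similar polyploid crops. Classifies reference genes as core or
    dispensable from best-hit protein similarity and coverage across variety
    proteomes; computes per-gene nucleotide diversity and two-population
    Hudson Fst with differentiation classification; filters, z-scores and
    k-means-clusters expression matrices and computes expression breadth;
    builds TSS-anchored multi-mark chromatin signal matrices, clusters
    chromatin states and calls H3K4me3/H3K27me3 bivalency; estimates Ka/Ks
    for homeolog pairs by codon-aware alignment and the Nei-Gojobori (1986)
    method; infers a TF-centered regulatory network by tree-ensemble
    importance with co-expression modules, hub detection and promoter motif
    scanning; and performs hypergeometric over-representation tests with
    Benjamini-Hochberg FDR. Includes a synthetic-data generator that plants
    known truth at every stage so the whole pipeline is testable end to end
    without external accessions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    ranger,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
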