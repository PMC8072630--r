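Package: skipnet
Title: Neural-Network Detection of Targeted Exon Skipping from RNA-Seq Read
    Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects a single targeted exon-skipping event (the MET exon 14
    skipping driver of non-small cell lung cancer) from RNA-seq alignments.
    Reads overlapping the gene locus are extracted, partitioned into
    fixed-size random read groups, and summarised as k-mer count or per-base
    exon coverage vectors; small dense and one-dimensional convolutional
    networks classify each group as wild type or exon-skipped, and a sparsely
    connected autoencoder with one latent node per exon projects groups into
    an exon-structured latent space for discovery of non-canonical isoforms
    such as LINE1 fusion chimeras. A paired-end read simulator generates
    labelled wild-type, exon-14-skipped and chimeric read sets so the whole
    pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    cluster,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
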