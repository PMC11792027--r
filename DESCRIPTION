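Package: isoformatlas
Title: Long-Read Transcriptome Refinement and Multi-Layer Differential RNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building tissue-specific transcriptome annotations from
    nanopore direct RNA sequencing long reads and testing condition-dependent
    RNA regulation at four layers. Long spliced reads are filtered by alignment
    deletion load, anchored at transcription start sites using ATAC-seq open
    chromatin peaks, corrected against short-read splice junctions, and
    collapsed into de novo transcript models. De novo transcripts are
    classified against a reference annotation with a GffCompare-style class
    code scheme (novel genes, tissue-specific and dominant transcripts), and
    differences between conditions are assessed for transcript expression
    (Fisher's exact test on CPM-normalized counts), alternative splicing
    events (ES, IR, ALT5, ALT3, AF, AL, MX), poly(A) tail-length shifts, and
    m6A modification at DRACH-motif sites, including metagene positioning over
    5'UTR/CDS/3'UTR. A seeded synthetic-data generator with recorded ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
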