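Package: epibivalent
Title: Super-Bivalent Chromatin Calling and Epigenome Comparison for
    Pluripotent States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies gene promoters by bivalent chromatin state from
    H3K4me3 and H3K27me3 ChIP-seq read intervals: RPKM enrichment over
    promoter windows and genome-wide 10-kb bins, per-sample Z-score
    normalization against a housekeeping-gene baseline, and calling of
    super-bivalent genes (broad, strong H3K4me3 together with strong
    H3K27me3). Also provides housekeeping-normalized TSS meta-profiles,
    bin-level whole-genome bisulfite methylation with hierarchical
    clustering under uncentered correlation, a one-versus-rest fold-change
    classifier for three-group expression matrices, and a synthetic-data
    generator with planted ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
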