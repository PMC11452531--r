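Package: broadbind
Title: Broad Binding Region Calling and Replication-Stress Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls broad binding regions (BBRs) from ChIP-seq peak calls by
    gap-merging peaks within a maximum distance, ranks them by a cumulative
    -log10 P score, assigns them to gene models with gene-size
    classification, and quantifies their overlap with external region sets
    such as mitotic DNA synthesis (MiDAS) regions, copy-number-variant
    hotspots and late-replicating intervals. Also builds binned ChIP signal
    tracks, log2 sample/input ratios and TSS-anchored signal matrices, and
    integrates two-genotype expression tables with threshold-based
    differential-expression classification. Ships a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
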