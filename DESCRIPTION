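Package: svbreaks
Title: Structural Variant Breakpoint Discovery from Long-Insert Mate-Pair Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chromosomal breakpoints from long-insert (4-6 kb)
    mate-pair sequencing data. Models the insert-size distribution of
    concordant pairs (0.5-99.5 percentile bounds), classifies mate pairs as
    consistent or inconsistent, and clusters inconsistent pairs into
    deletion, insertion, inversion, and translocation calls using greedy
    grid clustering followed by single-linkage refinement. Includes
    breakpoint set algebra (intersection, difference, multi-sample
    reporting, germline/somatic triage against polymorphism panels),
    ROC-type benchmark curves over supporting-pair thresholds, a
    permutation test for enrichment of epigenomic features around
    breakpoints, and a seeded coordinate-level mate-pair simulator for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
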