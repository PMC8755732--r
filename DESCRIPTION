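Package: wesbench
Title: Benchmarking Toolkit for Whole-Exome Capture Protocol Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluation computations for comparing whole-exome capture
    protocols and probe designs: BED interval arithmetic with three-way Venn
    partitioning of capture designs, small-variant benchmarking against a
    truth set via a joint SNV/indel confusion matrix with sensitivity,
    precision and F-measure, Jaccard (intersection-over-union) concordance
    matrices between call sets, coverage-at-depth and GC-bias density
    summaries from depth tracks, and pool-balance statistics for multiplexed
    enrichment. A synthetic-data generator produces capture targets with GC
    content, diploid truth and called variant sets under a parameterised
    error model, GC-biased depth profiles and pool read-total tables, so the
    whole evaluation pipeline is exercisable and testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
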