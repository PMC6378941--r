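Package: mdtrio
Title: Minimum-Distance Detection of De Novo Deletions in Trio Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects de novo heterozygous copy-number deletions in
    parent-offspring trios sequenced on capture-based targeted platforms.
    Implements coverage-adaptive binning (bins sized so the median read
    count across a sample subsample reaches a target), normalization of
    read counts to M scores (log2, median polish, loess adjustment for GC
    and mappability), the per-trio minimum-distance statistic that cancels
    inherited copy-number events, circular binary segmentation with
    permutation p-values and SD-undo pruning, candidate filtering with a
    population-variability flag, and read-pair evidence inspection.  A
    synthetic-data module simulates paired-end capture reads for trios and
    runs a spike-in benchmark in which reads overlapping a deletion are
    dropped with probability 0.5, scored by overlap fraction against the
    spiked truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
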