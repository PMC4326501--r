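Package: editkit
Title: A-to-I MicroRNA Editing Detection and ADAR-Dependent Expression
    Profiling from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of a small-RNA-seq analysis
    pipeline for adenosine-to-inosine (A-to-I) editing in mature microRNAs
    and for ADAR2-dependent miRNA expression changes. Reads are quality
    filtered, adaptor trimmed, length gated and 3'-trimmed, then aligned to
    a mature-miRNA reference under a one-mismatch/phred-30 policy.
    Per-position base tallies feed a binomial overrepresentation test
    against the sequencing-error null to call editing sites with editing
    levels, ND handling and seed annotation. Expression profiles are
    TMM-normalized and compared with an exact conditional Poisson test with
    Bonferroni correction, log2[(A+1)/(B+1)] fold-changes and the
    selection/reversal filters used for onco-miR profiling. Auxiliary
    statistics (microarray probe selection with BH FDR, 2^-ddCt relative
    quantification, Sanger peak-ratio editing levels) and a synthetic-data
    generator with planted editing sites and fold-changes are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    edgeR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
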