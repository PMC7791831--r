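Package: nanostoich
Title: Single-Base m6A Detection and Stoichiometry from Nanopore Direct
    RNA Signal Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) at single-base, single-read
    resolution from segmented Nanopore direct RNA sequencing current
    signals.  Per-motif gradient-boosted tree classifiers are trained over
    the twelve RRACH 5-mers from per-base signal features (mean, median,
    standard deviation, dwell), per-read calls are aggregated into
    per-site stoichiometry with a modified-read support filter, and
    transcript coordinates are mapped to the genome through alignment
    CIGAR strings.  Downstream summaries cover metagene distributions,
    exon-length comparisons, expression-methylation correlation, and the
    coupling of methylation with alternative-polyadenylation isoforms
    defined by poly(A)-site clustering.  A synthetic-data generator with
    known ground truth supports calibration and validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    vctrs,
    jsonlite,
    xgboost,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
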