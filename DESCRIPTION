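Package: lanealign
Title: Lane-Parallel Pairwise Sequence Alignment with Saturating Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global (Needleman-Wunsch), semi-global, and local (Smith-Waterman)
    affine-gap pairwise alignment of protein or DNA sequences, computed by a
    scalar reference dynamic-programming engine and by three lane-parallel
    vector engines (striped, prefix scan, anti-diagonal) that emulate SIMD
    registers of configurable width using saturating fixed-width integer
    arithmetic. Includes an origin-shift (bias) scheme for 8-bit local
    alignment, automatic width escalation on score overflow, reusable query
    profiles, alignment statistics, full-table and last row/column result
    variants, a Parasail-style function-name dispatcher, an enhanced
    suffix-array exact-seed filter, a batch FASTA/FASTQ aligner with GCUPS
    accounting, and a cross-verification harness that compares every vector
    configuration against the scalar reference cell by cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    parallel,
    tibble,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
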