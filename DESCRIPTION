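Package: fmalign
Title: FM-Index Short-Read Alignment with Difference-Bound Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a Burrows-Wheeler/FM index over a 2-bit packed reference
    genome and aligns short sequencing reads against it with a memory-frugal,
    difference-bound depth-first inexact search supporting mismatches and
    gapped alignment, a breadth-first reference implementation, and a
    seed-fragmented multi-phase search with a ranked partial-hit store.
    Includes SA-interval resolution to SAM records for single- and paired-end
    libraries, a wgsim-style paired-end read simulator with truth tracking,
    and a mapping-accuracy evaluator at a Phred-scale mapping-quality
    threshold.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
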