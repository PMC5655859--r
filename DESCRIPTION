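Package: omsv
Title: Structural Variant Detection from Simulated Optical Genome Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of next-generation optical genome
    mapping (NGM) structural variant detection. Simulates nick-labeled long DNA
    molecules from in-silico digested or synthetic references under a
    parametric error model, assembles them de novo into haplotype-aware
    consensus genome maps with an Overlap-Layout-Consensus pipeline using
    staged P-value cutoffs, aligns consensus maps to a reference by dynamic
    programming with empirical P-values, and calls large deletions,
    insertions, inversions and translocations with breakpoint-uncertainty
    intervals and zygosity. Includes a synthetic cohort generator emulating an
    X-linked dystrophinopathy case series and concordance scoring against
    planted truth, plus BNX/CMAP/SMAP-dialect text I/O.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
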