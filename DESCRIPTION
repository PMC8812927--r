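Package: polishr
Title: Repeat-Aware Short-Read Polishing of Long-Read Bacterial Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects residual small-scale errors in long-read bacterial
    genome assemblies using short-read alignments produced in
    all-alignments-per-read mode. Builds a per-position pileup with
    homopolymer-aware alignment end trimming and fractional read depth
    (reads with k alignments contribute 1/k depth), then applies a
    conservative threshold rule that changes a base only when the reads
    indicate a single unambiguous alternative. Includes a self-contained
    fixture simulator (genomes with planted repeats, calibrated error
    injection, error-free read tiling, an exhaustive edit-distance
    aligner emitting SAM) and reference-based assembly assessment
    (global-alignment error counts, identity and Q-scores, repeat
    annotation, polishing confusion matrices).
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    data.table,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
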