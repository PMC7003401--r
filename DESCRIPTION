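Package: sarcall
Title: Reference-Free Somatic SNV Calling with Generalised Suffix Arrays
Version: 0.1.0
Authors@R:
    person("sarcall", "maintainers", email = "sarcall@example.org",
           role = c("aut", "cre"))
Description: Detects tumour-exclusive single nucleotide variants from paired
    tumour-control short-read data without read mapping, by partitioning a
    generalised suffix array of the reads into common-prefix sections,
    extracting tumour-enriched sections through a dual suffix array design,
    building phred-filtered consensus pairs, filtering false positives, and
    reporting SNV coordinates against a reference used only for exact-match
    prefiltering and final coordinate calling. Ships a paired tumour-control
    read simulator with implanted single and clustered SNVs, a truth-VCF
    writer, and a precision/recall evaluator including cluster-size-stratified
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics
SystemRequirements: C++17
Config/testthat/edition: 3
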