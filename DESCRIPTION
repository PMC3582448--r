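Package: lincsvm
Title: Sequence-Feature SVM Classification of Long Intergenic Non-Coding RNA
    Transcripts
Version: 0.1.0
Authors@R:
    person("lincsvm", "developers", email = "lincsvm@example.org",
           role = c("aut", "cre"))
Description: Separates long intergenic non-coding RNA (lincRNA) transcripts
    from protein-coding transcripts using a binary radial-basis-function
    support vector machine over sequence-derived features: mean per-base
    conservation over exons, longest open reading frame (ORF) length and
    proportion, and the frequencies of a small set of di- and tri-nucleotide
    words. Provides parsers for BED/GTF/GFF transcript structures, FASTA
    genomes and WIG/bedGraph conservation tracks; spliced strand-aware
    sequence extraction; model training with grid search and stratified
    cross-validation; Platt-calibrated non-coding scores; sensitivity,
    specificity, Matthews correlation and ROC/AUC evaluation; a synthetic
    two-class corpus generator so the full pipeline is testable offline; and
    a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
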