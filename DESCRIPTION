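Package: circofossil
Title: Screening Genome Assemblies for Endogenous Circoviral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a genomic-fossil screen for
    circovirus-derived sequences (CVe) in animal genome assemblies. Provides a
    two-step translated homology search (six-frame Smith-Waterman of Rep/Cap
    polypeptide probes against contigs, then classification of extracted
    peptides against a curated reference library), locus annotation (fragment
    merging, flank-based CVe status, coding-intactness calls, stable CVe
    identifiers with cross-species orthology), host-association analysis on
    Rep phylogenies (parsimony host-switch counts, detection of conflicting
    metagenomic host labels, ortholog-based minimum-age calibration), and a
    synthetic-data generator that plants decayed viral insertions with full
    truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phytools,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    phangorn,
    jsonlite
Config/testthat/edition: 3
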