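Package: ribocef
Title: Contact Enrichment and Phylogenetic Contrasts for 30S Ribosomal
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of the amino-acid composition of small-
    subunit (30S) bacterial ribosomal proteins. Computes per-sequence
    composition, chemical-category fractions and net charge from aligned
    FASTA; detects protein-rRNA contact residues in 30S crystal structures
    with an all-atom distance cutoff and projects conservative contact
    sites across species through the alignment; quantifies interface
    preferences with the Contact Enrichment Factor (the ratio of a
    residue's contact-site proportion to its overall proportion); and
    tests thermophile/mesophile differences with phylogenetic independent
    contrasts of a binary temperature trait, using one-sample t-tests and
    exact binomial sign tests. A synthetic-data generator produces trees,
    temperature traits, trait-shifted proteomes and toy protein-RNA
    complexes with known contact ground truth, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
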