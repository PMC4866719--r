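Package: mitocomp
Title: Comparative Mitogenomics of Clitellate Annelids
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes, built around the 37-gene single-strand organization of clitellate
    annelids (earthworms and leeches). Provides a GenBank flat-file data model
    with rule-based curation of start codons and incomplete (polyadenylation-
    completed) stop codons, circular gene-order normalization and detection of
    rearrangement events (translocations, adjacent swaps, inversions, tRNA
    duplications and losses, syntenic blocks), codon counting under the
    invertebrate mitochondrial genetic code, an exact conditional R x 2 test
    of codon-usage homogeneity with a pruned-enumeration engine that scales to
    hundreds of codons across many genomes, a progressive search for maximal
    homogeneous genome subgroups, characterization of duplicated tRNA copies
    and of the putative control region, and a seeded synthetic-mitogenome
    generator for end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
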