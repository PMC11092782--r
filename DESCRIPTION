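Package: exonscout
Title: Comparative Discovery of Unannotated Exons from Protein Isoform Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies protein-coding exons that are present in the genome of
    one species but absent from its known protein isoforms, by comparative
    analysis of splice-aware isoform multiple sequence alignments. Per-species
    isoform alignments are collapsed into all-exon consensus rows with genomic
    codon coordinates, exon blocks missing in a species are detected, and their
    homologs are located by translated Smith-Waterman alignment inside the
    genomic window bounded by the neighboring exons. Includes novelty
    classification against CDS annotation tracks, transitive annotation
    scoring, exon-divergence statistics, BED/report writers, and a synthetic
    gene-family simulator with planted hidden exons for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
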