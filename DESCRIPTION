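Package: pointcen
Title: Population Genetics of Yeast Point Centromeres
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for the population genetics of Saccharomyces
    point centromeres. Annotates CDEI/CDEII/CDEIII elements from degenerate
    consensus motifs, computes missing-data-aware polymorphism and divergence
    statistics (segregating sites, nucleotide diversity, Watterson's theta,
    Dxy) from per-locus multiple sequence alignments, detects recombination
    with the four-gamete test together with a Hudson-Kaplan lower bound and
    an exact minimum-homoplasy-set search backed by a randomization null,
    characterises the polarized mutation spectrum (base-composition
    normalised relative substitution rates with locus bootstrap, and
    homopolymer-aware indel classification), and simulates coalescent
    alignments with the statistical structure of centromere resequencing
    data so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
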