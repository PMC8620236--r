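Package: retropop
Title: Population Genetics and Phylogenetics of Polymorphic Transposable Element Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-level analysis of transposable element (TE)
    insertion polymorphisms called from short-read data. Implements a cascading
    quality filter for mobile-element insertion calls (REF- insertion and REF+
    deletion dialects), construction of merged genotype matrices, majority-rule
    consensus building with CpG restoration and segmental-duplication
    deduplication, Kimura two-parameter repeat landscapes, clustering of
    identical SINE copies with flank-based discrimination of retrotransposition
    from segmental duplication, irreversible (Camin-Sokal) parsimony on binary
    presence/absence matrices with consistency/homoplasy indices, bootstrap and
    branch mapping with per-node heterozygosity, and TE-marker population
    genetics (individual heterozygosity, Nei's D, Wright and Weir-Cockerham
    Fst, PCA/PCoA, TE-vs-SNP concordance). Includes a synthetic-data generator
    that simulates TE insertions along a species tree so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
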