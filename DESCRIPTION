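Package: ProphageKit
Title: Prophage Discovery, Phenotype Statistics and Host-Phage Cophylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing temperate bacteriophages from genomic
    and phenotypic data. Detects integrated prophages from paired attachment
    site (attL/attR) direct repeats and locates attB sites in phage-free
    genomes; profiles GC content in windows and tests early-region GC
    depletion across a phage panel; computes VIRIDIC-style intergenomic
    nucleotide similarity with threshold clustering; estimates virulence
    (reduction in bacterial growth), host-range grades and one-step growth
    parameters (latent period, burst size) with the associated ANOVA and
    contrast structure; and reconciles phage and host phylogenies under an
    undated duplication-transfer-loss maximum-parsimony model with MPR
    counting, enumeration, clustering, cost-space exploration and a
    permutation null. A synthetic-data module simulates lysogenized genomes,
    infection dynamics and cophylogeny scenarios so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    deSolve,
    cluster,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
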