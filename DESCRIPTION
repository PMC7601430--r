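Package: wssgblup
Title: Weighted Single-Step GBLUP Genome-Wide Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic BLUP (ssGBLUP) and weighted single-step
    genome-wide association (WssGWAS) for pedigreed, partially genotyped
    populations. Builds pedigree numerator relationship matrices and their
    sparse inverses, VanRaden genomic relationship matrices with per-marker
    weights, the blended H-inverse that joins pedigree and genomic
    information, and solves the single-trait animal-model mixed-model
    equations. Marker effects are back-solved from breeding values and
    iteratively re-weighted in blocks of adjacent SNPs; the share of additive
    genetic variance explained by each SNP window is reported and windows
    above a threshold are selected as candidate QTL. Includes a gene-dropping
    simulator for pedigrees, genotypes and phenotypes, quality-control
    filters with per-filter accounting, window-to-gene mapping, bipartite
    trait-gene and miRNA-gene network construction, and a generic
    hypergeometric over-representation test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
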