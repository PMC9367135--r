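Package: methylcell
Title: Cell-Type Differential DNA Methylation Analysis from Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls cell differentially methylated regions (cDMRs) and cell
    lowly methylated regions (cLMRs) from Bismark-style per-CpG cytosine
    reports across sorted cell populations. Provides 1 kb genome tiling with
    pooled methylation rates and coverage filtering, a per-region two-factor
    (cell + animal) ANOVA with Benjamini-Hochberg correction, z-score based
    cLMR classification, gene-feature and CpG-island annotation with
    hypergeometric feature enrichment, methylation-expression correlation
    against seeded random backgrounds, gene-set and GWAS-SNP overlap
    enrichment, and a simplified PWM average-odds motif enrichment stage.
    A synthetic-data generator emulates every input with known ground truth
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
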