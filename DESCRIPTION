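Package: sweepscan
Title: Selective-Sweep Detection and Functional Enrichment in Two-Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed scan for selective sweeps between two diverged
    populations from diploid biallelic genotypes: per-site Weir-Cockerham
    F_ST and nucleotide diversity (pi), overlapping 20-kb windows, a
    Z-transformed composite of window F_ST and the log2 pi ratio with a
    Bonferroni genome-wide threshold, and merging of significant windows
    into directional sweep regions. Companion tools derive functional
    annotation tracks from a gene model, classify SNPs by category, bin
    sites by absolute allele-frequency difference (dAF) with log2
    fold-change (M-value) enrichment and chi-squared tests, run
    region-set overlap enrichment (one-sided Fisher with BH-FDR over a
    bin universe), call coding consequences of fixed differences, and
    genotype copy-number variants from region-versus-chromosome depth
    ratios. A synthetic-data module simulates Balding-Nichols diverged
    cohorts with planted sweeps, planted category enrichment and planted
    tandem duplications, with truth tables for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
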