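Package: lactascan
Title: Lactase-Persistence Allele Statistics and Locus-Specific Branch Length Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of the enhancer variants upstream of the
    lactase gene (LCT/MCM6) that confer lactase persistence. Computes
    per-population derived-allele frequencies with binomial standard errors and
    clamped confidence intervals, predicted lactase-persistence phenotype rates,
    exact Hardy-Weinberg tests, Weir-Cockerham FST, and a windowed
    locus-specific branch length (LSBL) selection scan with outlier calling and
    Benjamini-Hochberg correction. Includes haplotype-structure summaries
    (haplotype matrices and bifurcation trees around core alleles), a
    Balding-Nichols island-model genotype simulator with an injectable selected
    locus, and a bundled 18-population Sudanese/South Sudanese fixture of the
    nine enhancer-region SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
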