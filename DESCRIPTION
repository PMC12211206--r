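Package: degnull
Title: Genotype-Aware Differential Expression with a Randomized-Grouping
    Gamma Null
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline linking habitat, mitochondrial genotype
    (including heteroplasmy) and nuclear genotype to gene expression in a
    population sample. Implements an iterative hard-filter cascade for SNP
    genotype matrices with a mitochondrial/nuclear compartment partition,
    distance-based AMOVA with permutation significance, genotype PCA,
    per-locus Hedrick's G'ST, a self-contained negative-binomial Wald test
    for pairwise differential expression with median-of-ratios
    normalization and Benjamini-Hochberg correction, and a validation layer
    that compares observed differentially-expressed-gene counts against the
    0.95 quantile of a gamma distribution fitted (by AIC model selection)
    to counts from randomized sample groupings of identical size
    conformation. A synthetic-data module generates expression counts,
    genotypes and metadata with the statistical structure the analysis
    assumes, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
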