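Package: qtlmaf
Title: Genomic Heritability and Prediction Accuracy under MAF-Structured
    QTL Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how the minor
    allele frequency (MAF) of quantitative trait loci (QTLs) affects genomic
    heritability estimation and the accuracy of genomic estimated breeding
    values (GEBV). Provides an LD-structured half-sib family genotype
    simulator with U-shaped allele-frequency spectra and density-biased
    marker panels; MAF-stratified QTL sampling and trait simulation under
    gamma or equal-variance substitution-effect models; VanRaden, Yang
    (allele-frequency standardised) and LD-weighted genomic relationship
    matrices, including a MAF-partitioned pair; average-information REML for
    one- and two-component GBLUP models with AIC model comparison and GEBV
    prediction for masked test animals; and a replicated reference-test
    validation design summarising heritability estimates and TBV-GEBV
    correlations. Reads and writes PLINK text PED/MAP genotypes and
    GCTA-style plain-text relationship matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
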