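Package: popsep
Title: Supervised and Unsupervised Detection of Population Structure in SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the genetic separability of two candidate populations of
    SNP genotypes in sliding windows along the genome.  The unsupervised arm
    couples principal components analysis with the Hudson/Reich ratio-of-sums
    F_ST estimator, the Baik-Ben Arous-Peche (BBP) critical detection threshold
    1/sqrt(N*M), and a summed-ANOVA structure test with a global chi-squared
    p-value.  The supervised arm trains ensembles of three-layer feed-forward
    neural networks and a deterministic linear soft-margin support vector
    machine, reporting hold-out accuracy with ensemble confidence bands and ROC
    curves.  A Balding-Nichols simulator generates two-population genotype data
    with controlled divergence, including block-structured chromosomes and
    homogeneous null populations, for calibration and power studies.  Reads and
    writes PLINK text PED/MAP and delimited dosage tables.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
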