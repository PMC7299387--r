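Package: grspanel
Title: Panel-Based Genetic Risk Scores and Two-Population Comparison for
    Essential Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds unweighted and weighted genetic risk scores (GRS and
    wGRS) from a fixed panel of hypertension-associated SNPs, with
    effect-allele dosage coding, protective-allele orientation,
    dominant/recessive coding for single-group effect estimates, and
    expected-value imputation of missing genotypes.  Provides the
    population-genetic statistics needed to compare two populations on
    such a panel: allele-frequency estimation and chi-square comparison,
    Hardy-Weinberg equilibrium testing, EM-based haplotype-frequency
    linkage-disequilibrium estimation (r-squared), and the spectral
    effective-number-of-tests (Meff) multiple-testing correction.
    Includes score-distribution comparison (Mann-Whitney,
    Kolmogorov-Smirnov, quintile partition), rank-based inverse-normal
    phenotype transformation, score-phenotype regression models, and a
    two-population cohort simulator for end-to-end validation of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
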