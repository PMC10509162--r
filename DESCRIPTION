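Package: rnscan
Title: Genome Scans for Recent Natural Selection and Their Overlap with
    GWAS Predisposing Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of recent natural selection from
    multi-population genotype panels using a principal-component-based
    Mahalanobis outlier scan with genomic-control calibration, and a
    Weir-Cockerham FST scan with a trimmed chi-square null for
    cross-validation. Links selection signals to disease predisposing
    variation from GWAS summary statistics: Fisher enrichment across
    association thresholds, MAF-controlled partial Spearman correlation
    with permutation nulls, derived-allele polarization and direction-bias
    tests, and selection-stratified polygenic scores on case-control
    cohorts with matched-SNP empirical nulls. Includes a Balding-Nichols
    synthetic-data generator with planted selection and association
    signals for calibration and power studies.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
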