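Package: ivmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-sample Mendelian randomization (MR) on GWAS
    summary statistics, built around inflammatory-bowel-disease style
    case-control outcomes. Reads and harmonizes per-SNP association
    tables (allele alignment, strand complementing, palindromic-SNP
    handling), prunes instruments by p-value and linkage-disequilibrium
    R-squared, and fits causal effects with a likelihood-based estimator
    plus inverse-variance-weighted, MR-Egger, weighted-median and
    mode-based sensitivity estimators. Includes the MR-PRESSO global,
    outlier and distortion resampling tests, Cochran Q heterogeneity,
    fixed-effect disease-subtype heterogeneity tests, a-priori power and
    minimum detectable odds ratios for binary outcomes, a synthetic
    summary-statistic generator with controllable pleiotropy, and a
    study pipeline that orchestrates all of the above and emits result
    and plot-data tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
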