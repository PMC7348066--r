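Package: pleioscan
Title: Cross-Trait Shared-Gene Discovery from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A three-stage pipeline for finding genes shared by two complex
    diseases from genome-wide association study (GWAS) summary statistics: an
    LD-aware, simulation-based gene association test (per-SNP p-values are
    converted to 1-df chi-square statistics, summed per gene, and referred to
    a multivariate-normal null whose covariance is the reference-panel LD
    matrix, with adaptive Monte Carlo resampling); Fisher's-method
    cross-trait meta-analysis of per-gene p-values with layered Bonferroni
    control; and a case-control differential-expression concordance filter
    over multiple expression studies. Includes an LD-block synthetic-data
    generator so the whole pipeline runs and can be validated offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
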