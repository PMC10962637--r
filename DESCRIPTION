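Package: twasscan
Title: Transcriptome-Wide Selection Scans from Ancient DNA Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects natural selection on gene expression over an ancient-DNA
    time transect. Predicted expression is computed per individual from sparse
    cis-eQTL weight models and regressed on sample age; genomic control and
    Benjamini-Hochberg FDR calibrate the scan. Supporting analyses include a
    gene-level imputation-quality statistic with quantile filtering, a SNP-level
    selection-coefficient window scan with gamma-fit p-values and peak merging,
    gene-level aggregation of normalized haplotype selection statistics
    (iHS/SDS), and a permutation test for concordance between predicted and
    observed expression across populations. A seeded Wright-Fisher synthetic
    cohort generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
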