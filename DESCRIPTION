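Package: bumfdr
Title: Variability of False Discovery Rate Estimates in Correlated
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-group, block-correlated log2 gene expression
    data with known differential-expression ground truth, estimates the
    false discovery rate from gene-level t-test p-values with a
    beta-uniform mixture (BUM) model, and quantifies how sample size,
    correlation block size, and the true proportion of differentially
    expressed genes drive both the magnitude and the precision of
    FDR-related estimates: the BUM shape and uniform-weight parameters,
    the logical upper bound on the true-null proportion, the observed
    false discovery proportion, Efron's dispersion variate A, and the
    spread of the empirical pairwise-correlation density. Includes a
    factorial experiment driver and a subsample-resampling protocol for
    studying the stability of FDR-targeting p-value cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
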