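Package: normagene
Title: Reference-Gene-Free Normalization of qPCR Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven normalization of relative qPCR expression values
    without reference (housekeeping) genes. Within each treatment a
    replicate-level multiplicative bias is estimated by least squares on the
    log-transformed target-gene panel and divided out, with first-order
    uncertainty on the fitted bias and full tolerance of missing cells.
    Includes the classical reference-gene baseline (geometric-mean
    normalization factor), a lognormal simulator of artificial qPCR
    data-sets with known truth, Monte-Carlo benchmarking of the two
    normalization strategies (variance reduction and
    closer-to-the-true-mean proportions over a bias-to-variation grid), and
    theoretical stability curves for the dependence of normalization
    precision on panel size.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
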