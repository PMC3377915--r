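Package: ecdselect
Title: Extreme Class Discrimination Feature Selection for Paired Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for paired two-class expression data (for
    example tumour and adjacent normal tissue from the same patients).
    Implements cross-class normalization, a modified Wilcoxon signed-rank
    procedure with per-feature misclassification accounting, a sign-symmetry
    binomial test with Bonferroni correction, and a pair-resampling bootstrap
    filter, combined into strict and relaxed extreme-class-discrimination
    selections. Includes baseline paired tests with false-discovery-rate
    ranking, hypergeometric overlap statistics for gene-list comparisons, and
    a random-effects simulator of paired intensities with known ground truth
    for power and error-rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
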