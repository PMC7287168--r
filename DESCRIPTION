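Package: methsite
Title: Sequence-Based Prediction of DNA N6-Methyladenine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N6-methyladenine (6mA) modification sites from
    fixed-width sequence windows centered on a candidate adenine. Sequences
    are encoded by two complementary feature representations - nucleotide
    positional specificity (per-position orthogonal binary codes plus
    position-independent k-mer frequencies) and pseudo dinucleotide
    composition (dinucleotide frequencies plus physicochemical sequence-order
    correlation factors) - then fused, ranked by two-class ANOVA F-value,
    and reduced to the accuracy-optimal incremental feature subset before
    training a radial-basis-kernel support vector machine. Includes a
    stratified cross-validation harness reporting sensitivity, specificity,
    accuracy, Matthews correlation and ROC/AUC, a reproducible synthetic
    benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
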