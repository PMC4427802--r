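Package: serodiff
Title: Cross-Validated Differential Abundance Analysis of Serum Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a label-free serum-proteomics differential-abundance
    pipeline for distinguishing cholangiocarcinoma (CCA) from benign biliary
    tract disease (BBTD): log2/median/quantile normalization of a protein-by-
    sample intensity matrix, k-fold cross-validated Welch-test intersection
    selection of differentially expressed proteins, unsupervised validation
    views (hierarchical clustering, PCA, volcano coordinates, box summaries),
    cohort-level clinical comparisons, and an audit tool for published
    mean/SD/n summary tables. A synthetic-data generator reproduces the
    statistical structure of a 19-CCA versus 17-BBTD cohort so every stage is
    testable without patient data.
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
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
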