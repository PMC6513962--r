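Package: dcnet
Title: Differential Co-Expression Network Analysis for Two-Condition
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects gene pairs whose co-expression changes between two
    conditions (e.g. disease and normal brain) using the Fisher
    z-transformation correlation-difference test with
    Benjamini-Yekutieli false discovery rate control, classifies each
    change (condition-specific, strengthened, weakened, sign-reversed),
    aggregates pair-level changes into dysregulated hub genes, assembles
    a core dysregulation network, associates genes with clinical traits
    via first-order partial correlation, and quantifies cross-species
    co-expression conservation. Includes preprocessing (quantile
    normalization, linear-model covariate adjustment, batch centering,
    outlier flagging) and a synthetic-data generator with planted
    correlation structure so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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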