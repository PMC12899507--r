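Package: droughtrank
Title: Drought-Tolerance Screening and Trait-Transcriptome Integration for
    Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for evaluating drought tolerance across crop germplasm
    panels and linking physiological responses to transcriptome structure.
    Implements germination-index screening with K-means tolerance grouping,
    fuzzy-membership standardization with composite D scores, grey
    relational analysis ranking, differential-expression set logic with
    hypergeometric gene-set enrichment, correlation-network module
    detection with module-trait correlation and hub-gene extraction,
    Mantel permutation tests, and qPCR relative-expression concordance.
    A seeded synthetic-data generator reproduces the statistical structure
    of a multi-variety drought experiment so the whole pipeline can be
    exercised and validated without access to raw sequencing data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    withr
Config/testthat/edition: 3
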