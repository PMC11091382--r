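Package: errmir
Title: Batch-Robust miRNA Expression-Ratio Biomarkers via Regulatory
    Network Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers batch-insensitive diagnostic biomarkers from small
    RNA-seq profiles by forming within-sample expression ratios (ERRmiR
    features) of miRNA pairs connected through a transcription-factor-
    mediated miRNA-miRNA interaction network. Provides network composition
    from miRNA->TF and TF->miRNA regulation tables, precursor-to-mature
    identifier mapping, reads-per-million normalisation, low-abundance
    filtering, ratio-feature generation, cross-batch stability
    diagnostics, univariate differential screening, repeated genetic-
    algorithm wrapper feature selection with frequency tallying, support-
    vector classification with ROC/AUC evaluation and learning curves,
    and a synthetic multi-batch data generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
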