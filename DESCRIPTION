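Package: greenview
Title: Semantic Naturalness Scoring of Street-Level Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing the Calculated Semantic Naturalness (CSN)
    metric from image-classifier label lists and relating it to human Perceived
    Naturalness (PN) ratings and small-area deprivation indices. Includes a
    label-to-semantic-class taxonomy registry, per-image CSN scoring and corpus
    summaries, pseudo-random geospatial sampling of a study polygon with
    nearest-panorama matching and virtual-camera requests, Likert panel
    aggregation with distributional diagnostics, Pearson correlations with
    Fisher-z confidence intervals, end-to-end experiment runners, and a fully
    synthetic world generator (street network, naturalness field, mock image
    classifier, mock rating panel, mock deprivation lookup) so the whole
    pipeline is testable without any external imagery or classification
    service.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
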