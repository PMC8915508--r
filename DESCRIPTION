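Package: losnet
Title: Network Features for Predicting Hospital Length of Stay at Admission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting hospital length of stay (LOS) for elderly
    patients with chronic diseases using only information available at the
    point of admission. Builds a multimorbidity network from discharge
    records with relative-risk edge weights and Katz-style confidence
    intervals, a blocked Jaccard k-nearest-neighbour patient similarity
    network, and four groups of engineered features (baseline, historical,
    network centrality and disease risk, neighbour LOS statistics).
    Includes supervised linear discriminant compression of the centrality
    block, an ablation and evaluation harness over pluggable regressors,
    and a synthetic discharge-record generator with planted co-occurrence
    and LOS structure for end-to-end validation.
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
    lubridate,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    e1071,
    igraph,
    MASS,
    optparse,
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
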