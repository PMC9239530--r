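Package: wsirs
Title: Whole-Slide Image Features for Oncotype DX Recurrence Score Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline from cell-level detections in breast-cancer
    H&E whole-slide images to Oncotype DX Recurrence Score (RS) correlation.
    Provides fixed-grid tiling with tissue masking and per-tile tumor/TIL density
    maps; extraction of 32 slide-level image features (tile-wise tumor count, TIL
    count and tumor percentage over the ten densest tiles, TIL number variance,
    and a rule-based aggregated nuclear grade anchored to a reference TIL nucleus
    area); OLS and LASSO regression of RS on Magee-equation-2 clinicopathological
    variables plus image features with adjusted R-squared feature selection;
    TAILORx risk stratification with three-by-three concordance and chemotherapy
    recommendation discordance statistics; detection and segmentation evaluation
    (greedy point matching, IOU-cutoff contour matching, Hausdorff distance,
    equivalent diameter); and seeded synthetic scene and cohort generators so the
    whole chain is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    polyclip,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr
Suggests:
    EBImage,
    mgcv,
    pracma,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
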