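Package: droughtDHI
Title: Dynamic Habitat Indices for Drought Assessment of Coniferous Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the three Dynamic Habitat Index components (annual
    cumulative productivity, minimum cover, seasonality) from dense NDVI
    composite time series, derives de Martonne aridity zonation from monthly
    climate grids, classifies per-pixel multi-year trends (Theil-Sen and
    moving-window OLS), tabulates positive-to-negative trend ratios by
    aridity zone and forest health status, and fits a binomial logistic
    model of health status with collinearity filtering (correlation and
    variance inflation), McFadden's pseudo R-squared and variable-importance
    ranking. Includes a synthetic-scene generator with known ground truth
    (seasonal NDVI sinusoids with drought-year suppression, altitude-coupled
    climate fields, aridity-coupled damage masks) so every stage of the
    workflow can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    car,
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
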