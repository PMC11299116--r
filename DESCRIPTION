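Package: heatwarn
Title: Distributed-Lag Modelling and Early Warning of Heatstroke from Daily Weather
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing and forecasting daily heatstroke counts from
    meteorological series. Computes derived heat-exposure features (heat index,
    Magnus dew point, heatwave runs, sanfu-calendar flags), fits distributed
    lag non-linear models (DLNM) with quasi-Poisson time-series regression and
    returns lag-specific and cumulative relative-risk surfaces with confidence
    intervals, performs Boruta shadow-feature selection, trains and evaluates a
    suite of count-prediction models (decision tree, bagged random forest,
    gradient boosting, linear SVR, rolling ARIMA), and drives a rule-based
    heat-health early-warning schedule. Includes a synthetic-data generator
    with a known distributed-lag exposure-response surface so the full
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    ranger,
    rpart,
    e1071,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
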