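Package: driftnet
Title: Directed Interaction Networks for Multi-Site Pollutant Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers directed, strength-weighted interaction networks between
    pollutant concentration time series measured at many monitoring sites.
    The framework scans the Pearson cross-correlation of each city pair over
    a grid of time lags to estimate the strength (maximum correlation) and
    temporal order (lag at the maximum) of a potential transport
    relationship, gates pairs with a t-test on the correlation and a Fisher
    r-to-z comparison of the lagged versus contemporaneous coefficients, and
    confirms the candidate direction with a bivariate Granger-causality
    F-test. Includes hourly-data quality control (implausible zeros,
    duplicate records, extreme outliers), station-to-city averaging,
    timezone harmonisation, monthly windowing, network export to CSV and
    GeoJSON, and a synthetic advection simulator with ground-truth lags for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
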