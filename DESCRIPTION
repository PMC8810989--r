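Package: lagoondate
Title: Dating Land Conversion to Waste Lagoons from Satellite Reflectance Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the construction year of swine waste lagoons (and similar
    land-to-water conversions) from per-pixel near-infrared surface reflectance
    time series. Implements cleaning of scaled surface reflectance records
    (bright-pixel removal, linear filtering), single-changepoint detection under
    a normal likelihood for change-in-mean and change-in-mean-and-variance
    costs, a decision workflow that maps the fitted changepoint to a calendar
    construction year or a pre-record class, and validation scoring with a
    configurable year tolerance. A spatial stage area-filters hydrography
    features, computes geodesic (WGS84) nearest-water distances, summarises
    them by construction cohort, tests monotonic trend with the Mann-Kendall
    statistic, and aggregates lagoon density by watershed polygon. A synthetic
    data module simulates Landsat-5-like band-4 series with known change dates,
    cloud dropout, bright outliers, and an early-record artifact, so the whole
    workflow is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    geosphere,
    sp,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
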