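Package: pondcast
Title: Pond Ecosystem State Estimation and Fish-Kill Risk Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predictive hydrochemical monitoring for aquaculture ponds. Couples a
    four-state phytoplankton-zooplankton-fish-dissolved-oxygen (P-Z-F-O) ordinary
    differential equation model with a constrained, adaptive Extended Kalman Filter
    driven by hourly dissolved-oxygen measurements. Includes local observability
    analysis from Lie derivatives, innovation-based noise adaptation with
    Mahalanobis anomaly gating, empirical chlorophyll-a and Secchi-depth proxies
    for plankton biomass, a synthetic sensor-stream generator, and an operative
    short-term forecasting layer (outlier elimination, least-squares trend fits,
    time-to-critical estimation, and species-specific alarm rules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
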