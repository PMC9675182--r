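Package: dtrheat
Title: Heatwave Detection and Projection from Diurnal Temperature Range Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heatwave events in daily district temperature series using
    a health-based diurnal temperature range (DTR) exceedance threshold with
    minimum mortality temperature (MMT) masking, characterises events
    (duration, peak, intensity), and projects future events by applying
    climate-scenario temperature anomalies (delta-change method) to observed
    series. Includes a synthetic daily weather generator with seasonal cycle,
    AR(1) persistence, coastal/inland DTR regimes and plantable ground-truth
    events, so the full pipeline is testable without restricted station data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
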