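Package: soilwb
Title: Daily Soil Water Balance Pipeline for Irrigated Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes manually collected field-trial data (daily weather,
    sparse multi-instrument NDVI, neutron-probe soil moisture and irrigation
    records) into daily soil moisture deficit and drainage predictions with a
    single-store bucket model. Canopy cover is derived from NDVI with a linear
    development assumption between emergence and closure; field capacity is
    estimated from winter-fallow probe readings; the balance is corrected by
    canopy-scaled potential evapotranspiration and by resetting to observed
    storage whenever a reading is available. Includes drainage-event detection
    for scheduling leachate sampling, a synthetic-trial generator with known
    ground truth, and a content-hash incremental stage runner so repeated runs
    execute only what changed.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
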