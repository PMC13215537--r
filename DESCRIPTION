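Package: dredgecarbon
Title: Probabilistic Estimates of Seabed Organic-Carbon Disturbance by
    Dredging and Aggregate Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonises heterogeneous seabed sediment-extraction records
    (port and harbour dredging, marine aggregate extraction) into a single
    event table in kilograms, imputes missing extraction masses from
    monetary cost or from a fitted log10-normal mass model, filters a
    georeferenced sediment total-organic-carbon (%TOC) sample library into
    context-specific empirical distributions, and propagates the combined
    uncertainty through a seeded Monte Carlo simulation to annual
    country-, shelf-, and port-level organic-carbon disturbance estimates
    with percentile bounds. Includes a synthetic-data generator that
    emulates the record missingness patterns and %TOC distributional
    structure the analysis assumes, so the whole pipeline is testable
    without external data.
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
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
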