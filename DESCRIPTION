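Package: icepop
Title: Sea-Ice Habitat Metrics and Stochastic Projections of Polar Bear
    Population Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the conservation status of polar bears
    (Ursus maritimus) from sea-ice habitat trends.  Computes the
    standardized habitat metric 'ice' (ice-covered days per year) from
    daily gridded sea-ice concentration, estimates generation length
    from live-capture records of adult females with cubs (with a
    yearling pseudo-observation rule and bootstrap uncertainty), fits
    log-linear relationships between changes in ice-covered days and
    proportional changes in subpopulation abundance at global and
    ecoregion scope, and runs seeded Monte Carlo projections of per cent
    change in mean global population size over three generations,
    scoring the outcome against IUCN Red List criterion A3 reduction
    thresholds.  A seeded synthetic-data generator emulates the
    statistical structure of the satellite, capture and abundance inputs
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
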