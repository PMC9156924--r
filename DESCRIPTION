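Package: broilerland
Title: Steady-State Demographics and Land-Use Scenarios for US Broiler
    Production
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A steady-state demographic box model of US broiler chicken
    production with direct and indirect land-use accounting. Computes
    flock populations, placement and slaughter rates, housing and
    feed-cropland footprints for fast-, intermediate- and slow-growing
    breeds under confined (CAFO), outdoor-access and pasture management,
    and solves for the national consumption level that holds total land
    use at the current baseline. Includes calibration of breed
    parameters from breeder performance-objective tables and a synthetic
    table generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
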