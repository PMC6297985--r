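Package: cuvetteflux
Title: Flux Inversion and Gas-Exchange Processing for Multiplexed
    Flow-Through Plant Cuvette Systems
Version: 0.1.0
Authors@R: person("VOC", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inversion of well-mixed flow-through
    cuvette gas dynamics for whole-plant volatilomics. Converts raw
    multiplexed valve-switched sensor logs (PTR-ToF-MS volatile organic
    compound channels, infra-red gas analyser CO2 and H2O channels) into
    leaf-area-normalized emission, net CO2 assimilation and transpiration
    rates: demultiplexing with lag-time discard, cubic-spline
    empty-cuvette background correction, bare-soil reference correction,
    air-exchange time constants, an evaporative-cooling energy balance,
    theoretical ion m/z assignment for soft chemical-ionization reaction
    channels, green-pixel leaf-area calibration, and a synthetic
    experiment generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
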