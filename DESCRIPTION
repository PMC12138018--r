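Package: heatvuln
Title: Commune-Level Heatwave Vulnerability Index and Heat-Morbidity Indicator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a commune-level heatwave vulnerability index from four
    oriented indicator layers (mean summer surface temperature, an FDep-style
    social deprivation score, the CORINE-coded artificial and non-vegetated
    surface fraction, and the air-conditioning equipment rate), standardised
    as Z-scores and combined with equal weights, together with a syndromic
    heat-morbidity indicator counting emergency department and emergency GP
    visits for hyperthermia and heatstroke, dehydration, and hyponatremia.
    Includes zonal statistics on administrative polygons, a deprivation score
    as the leading principal component of four standardised socioeconomic
    variables, quantile classing for choropleth mapping, and a fully seeded
    synthetic geodata generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
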