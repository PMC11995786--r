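Package: holoclim
Title: Site-Specific Holocene Climate Driver Series for Peatland Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates continuous, site-specific, sub-annual (monthly or
    weekly) climate driver series spanning the 12,000 years of the Holocene
    plus 100 years of projected future climate, for driving peatland
    ecohydrological models. Fits a stochastic daily weather generator to
    station observations, simulates arbitrarily long baseline series,
    modulates the historical portion with gridded 1000-year-resolution
    paleoclimate anomalies, modulates the final century with delta-change
    scalers derived from future climatologies, and computes potential
    evapotranspiration with a day-length- and interval-scaled Thornthwaite
    method plus net rainfall. Includes synthetic fixture generators so the
    whole pipeline runs and is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
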