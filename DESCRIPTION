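Package: esvland
Title: Ecosystem Services Valuation and Spatial Response Analysis for Land-Use Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how land-use transformation reshapes the
    monetary value of ecosystem services at regional scale. Implements
    categorical land-use change accounting (per-class areas, change rates and
    Markov-style transfer matrices), equivalent-factor valuation of ecosystem
    services per land class and per service function, and three spatial
    response analyses over zonal values: Global Moran's I with permutation
    inference, Getis-Ord Gi* hot/cold-spot classification, and the
    value-weighted center-of-gravity trajectory. Includes a synthetic
    landscape simulator driven by user-specified Markov transition matrices
    so the full pipeline is testable without proprietary remote-sensing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
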