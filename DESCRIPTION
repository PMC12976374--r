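Package: pahburden
Title: Probabilistic Dietary PAH4 Exposure Assessment and Cancer Burden Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for probabilistic assessment of dietary exposure
    to the four EU marker polycyclic aromatic hydrocarbons (PAH4:
    benz[a]anthracene, benzo[a]pyrene, benzo[b]fluoranthene, chrysene) from
    total-diet-study style data, and for the downstream cancer burden chain.
    Includes readers and validators for concentration, catalog and consumption
    survey tables; a synthetic total-diet-study data generator; a two-scenario
    (lower-bound / upper-bound non-detect substitution) Monte Carlo simulation
    of person-day PAH4 intake; distributional characterisation with exact
    one-dimensional two-means exposure classification and nonparametric tests;
    and the lifetime cancer risk, relative risk, population attributable
    fraction and attributable DALY calculation with minimal-risk-level
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
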