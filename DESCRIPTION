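Package: soilhealth
Title: Small-Area Association Analysis of Soil Metals, Deprivation and
    Respiratory Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small-area ("ecological") analysis pipeline for
    environmental-justice studies linking urban soil geochemistry, air
    pollution, socioeconomic deprivation and respiratory health. Aggregates
    point soil-sample geochemistry to reporting zones by geometric means,
    builds a composite soil metal index from per-metal decile scores (As, Cr,
    Ni, Pb, Se), computes age- and sex-standardised incidence ratios by
    indirect standardisation, reconstructs a multiple-deprivation decile index
    from domain rankings with the health domain excluded, and quantifies
    associations with Pearson correlation matrices (with n-dependent critical
    values) and log-link generalised linear models selected by AIC. Includes a
    fully synthetic study-region generator with known generating parameters so
    the whole pipeline is testable without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
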