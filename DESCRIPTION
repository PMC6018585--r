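Package: transppm
Title: Transient Dynamics and Non-Normality of Age-Structured Population Projection Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 18-bin Leslie-type population projection matrices from
    single-year age-specific counts of female population, deaths and births
    (Eurostat-shaped tables), and analyses their transient dynamics. Computes
    the damping ratio, case-specific reactivity and inertia on the
    growth-standardised matrix, three scalar matrix non-normality metrics
    (Frobenius commutator, Henrici, Ruhe) on raw and standardised matrices,
    and epsilon-pseudospectra as minimum-singular-value grids over the complex
    plane. Includes a synthetic demographic data generator with known vital
    rates for end-to-end validation, data-cleaning filters for implausible
    death records, and a multivariate comparison layer with Spearman
    correlations and principal component analysis using Horn's parallel
    analysis for component retention.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
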