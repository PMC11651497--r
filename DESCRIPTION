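Package: invivobe
Title: In Vivo Base Excess Stability Under Acute Carbon Dioxide Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of standard base excess (SBE) stability during acute
    in vivo CO2 titration. Implements the base-excess equation family
    (generalized buffer power, the conventional beta = 16.2, and the
    Schlichtig variant), pooled SBE-versus-PCO2 regression, multi-study
    analysis of covariance with a study-by-PCO2 interaction, and a
    buffer-power sweep whose zero-slope criterion locates the CO2-invariant
    in vivo base excess with a test-inversion confidence interval. A seeded
    synthetic CO2-titration generator supports parameter-recovery
    validation, and a command-line pipeline ties generation, SBE
    computation, calibration and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
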