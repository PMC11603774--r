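Package: ntaflow
Title: Non-Targeted LC-HRMS Feature-Table Processing for Exposome Studies
Version: 0.1.0
Authors@R:
    person("NTA", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable post-processing pipeline for non-targeted LC-HRMS
    (liquid chromatography high-resolution mass spectrometry) feature tables
    from paired human biomonitoring samples: adduct and blank filtering,
    detection-frequency cutoffs, cross-polarity (ESI+/ESI-) feature merging,
    creatinine normalization of urine, truncated-normal imputation of
    below-detection-limit values, parametric empirical-Bayes batch correction,
    MS2 spectral-library annotation with Schymanski-style confidence levels
    and source attribution, differential enrichment statistics with
    Benjamini-Hochberg control, and endogenous-exogenous chemical correlation
    networks. Includes a synthetic-cohort simulator with planted ground truth
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
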