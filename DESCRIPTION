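Package: soilhealth
Title: Soil Health Index Construction for Split-Factorial Saline Irrigation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds PCA-based soil health indices from plot-level agronomic
    trial data: minimum-data-set indicator selection (eigenvalue and
    variance-share retention, within-10-percent loading rule), linear 0-1
    indicator scoring, principal-component variance weighting, and the
    weighted additive index SHI = sum(w_i * s_i). Also provides the
    split-factorial (split-plot) ANOVA with whole-plot and subplot error
    strata, Tukey HSD compact letter displays and LSD interaction
    comparisons used to summarise such trials, and a seeded generator of
    synthetic saline-irrigation trials (tillage x deficit irrigation x
    straw mulch) with a latent-salinity covariance structure for testing
    the full pipeline without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
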