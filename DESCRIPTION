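Package: epfmix
Title: Mixture Bioassay Analysis for Entomopathogen-Insecticide Co-Applications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of two-agent mixture bioassays against insect pests,
    built around the independent-action (Bliss) reference model. Fits
    single-agent log-logistic concentration-response curves by binomial
    maximum likelihood or least squares, computes Schneider-Orelli corrected
    mortality and Bliss expected mixture mortality, fits independent-action
    response surfaces with absolute, dose-ratio and dose-level deviation
    terms, selects among nested surface models by likelihood-ratio tests,
    classifies synergism and antagonism across the dose plane, estimates
    lethal times (LT50) from interval-censored time-mortality data with a
    four-parameter probit-on-log-time model, and pools replicate bioassays
    after a two-way ANOVA with Bonferroni-adjusted pairwise contrasts. A
    synthetic bioassay generator reproduces the replicated leaf-cohort
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
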