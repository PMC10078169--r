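Package: jsclimate
Title: Integrated Jolly-Seber Models with Climate Trends and Population
    Viability Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian analysis of open songbird populations from integrated
    mark-resight and count data. Implements a data-augmented Jolly-Seber
    model that combines individual capture-resight histories of marked
    females with yearly counts of unmarked females, with logit-linear time
    or climate trends on per-capita recruitment and age-specific apparent
    survival, density-dependent recruitment, ambiguous age classification,
    and measurement error in plot-level climate covariates predicted from
    elevation-graded weather-station series. Includes a custom
    Metropolis-within-Gibbs sampler with exact per-individual updates of the
    latent entry and survival states, convergence diagnostics, a synthetic
    data generator matching the assumed generative process, and statistical
    forecasting of abundance and local extinction risk to a horizon year.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
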