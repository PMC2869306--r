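Package: igt
Title: Inductive Game Theory for Multiparty Conflict Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts candidate conflict decision-making strategies from event
    time series of multiparty fights. Estimates cross-fight membership
    correlations against a Monte Carlo time-shuffle null, builds (n,k) plus
    combinator strategy models from those correlations, simulates the models
    as conflict cascades, and scores them against observed data with
    fight-size distributions, shuffle and coarse-graining perturbation tests,
    and population cost statistics. Includes a synthetic-data generator with
    known ground truth so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
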