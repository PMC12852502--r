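Package: streamsync
Title: Community Synchrony Analysis for Stream Macroinvertebrate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying temporal synchrony in multi-species
    community time series, built around the Loreau-de Mazancourt variance-ratio
    statistic. Provides Monte Carlo null tests of community synchrony,
    per-taxon contribution z-scores from single-column randomizations,
    temporal turnover and diversity metrics, environmental-variability
    summaries, Spearman association screens, Moran's I spatial autocorrelation,
    functional-feeding-group aggregation with a crossed random-effects model,
    and a NEON-shaped synthetic multi-site study generator so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
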