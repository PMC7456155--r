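Package: woodonset
Title: Environmental Drivers of Wood-Formation Onset in Northern Conifers
Version: 0.1.0
Authors@R:
    person("Forest", "Phenology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to model the springtime onset of wood formation
    (xylogenesis) in Northern Hemisphere conifers as a function of
    environmental drivers. Computes photoperiod, mean annual temperature,
    sigmoid thermal forcing units, chilling days, drought-index and
    precipitation predictors from daily climate series; fits linear
    mixed-effects models with crossed random intercepts for species and
    site; reports marginal and conditional R-squared, variance-inflation
    screening, AIC/BIC model comparison and subgroup fits; partitions
    explained variance among predictors (unique and orderings-averaged
    shares) and compares chilling-window definitions. Ships a synthetic
    data generator that emulates a 79-site, 21-species latitudinal design
    so the full pipeline is testable by parameter recovery without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
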