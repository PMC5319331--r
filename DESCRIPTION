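Package: sproutess
Title: Climate-Driven Evolution of Sprouting Probability in Dormancy-Prone Perennials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of sprouting probability in
    perennial plants capable of vegetative dormancy. Fits per-vital-rate
    generalized linear models with shrunken year effects and AICc-based
    exhaustive model selection, assembles function-based historical
    (stage-pair) and age-by-stage population projection matrices, screens
    vital rates for conspecific density dependence and calibrates a Ricker
    density modifier to an observed plateau density, locates evolutionarily
    stable sprouting strategies by resident-invader (pairwise invasibility)
    analysis with bootstrap standard errors, and forecasts the optimal
    sprouting trait and deterministic population growth rate under
    bias-corrected climate series, including a life table response
    decomposition of the growth-rate difference due to trait evolution.
    A synthetic-data module generates climate series and individual life
    histories with known parameters so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
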