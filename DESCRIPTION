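Package: soclearn
Title: Evolution of Social Learning in Density-Regulated, Age-Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Demographic models and individual-based simulations of the
    evolution of social versus individual learning in age-structured
    populations under environmental change. Provides two-age-class
    recursions with closed-form equilibria for density-dependent
    population regulation acting through fertility or through mortality,
    inversion routines that derive matched vital-rate parameters from
    target demographic quantities, a stochastic agent-based simulator of
    a heritable individual-learning propensity, per-step observables
    (adaptation by age class, effective vital rates, birth timing),
    replicated parameter sweeps with reproducible seeding, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
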