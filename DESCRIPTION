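Package: velutina
Title: Colony Dynamics, Imperfect Detection and Control of Invading Vespa
    velutina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing commune-scale invasions of the Asian hornet
    (Vespa velutina): classification of discovered nests as active or
    inactive from calendar cut-off rules, yearly colony counts and nest
    densities, habitat breakdowns, a density-dependent Poisson model of
    colony dynamics with year-varying binomial detection and destruction,
    Bayesian inference of the growth rate, carrying capacity and detection
    probabilities by Metropolis-Hastings MCMC, and equilibrium predictions
    of invasion size with and without nest destruction. Includes a
    synthetic-invasion generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
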