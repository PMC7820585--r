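Package: desperation
Title: Desperation-Threshold Model of Cooperation, Exploitation and Trust
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a state-dependent model of the choice between
    cooperating, exploiting others, and foraging alone, in which falling
    below a desperation threshold of resources carries a fixed fitness
    penalty. Optimal action policies over resources and population
    trustworthiness are computed by stochastic dynamic programming
    (backward induction on a discretised resource grid with Gaussian
    transition kernels). Populations of agents following the optimal
    policy are simulated with random interaction groups, punishment of
    exploiters, a mean-reverting resource perturbation, and social trust
    estimated by finite sampling of others' behaviour. Includes tools for
    classifying the two absorbing population equilibria (poverty trap and
    virtuous circle), phase-diagram parameter sweeps, critical
    first-round exploitation estimates, inequality-shock experiments, and
    group-size experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
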