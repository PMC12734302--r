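Package: gwbranch
Title: Galton-Watson Branching Processes for Ecology and Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical Galton-Watson branching process as used in
    ecology, epidemiology and population genetics: offspring laws (empirical,
    Poisson, geometric, negative binomial) with probability generating
    functions and moments; extinction probability as the smallest non-negative
    root of Q = G(Q), including the Lambert-W closed form for Poisson
    reproduction; the full distribution, conditional mean and variance of the
    extinction time; generation-t population-size distributions by iterated
    PGF composition; exact Wright-Fisher Markov-chain absorption analysis for
    small diploid populations with Kimura-Ohta diffusion approximations; the
    single selfing-individual model with haploid-phase selection; maximum
    likelihood estimation of the offspring mean and founding time from census
    trajectories and top-coded fertility tables; and a Monte Carlo simulator
    used as an independent check on every analytic result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
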