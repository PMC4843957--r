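Package: bayesqfa
Title: Bayesian Hierarchical Models for Quantitative Fitness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative fitness analysis (QFA) measures the growth of
    thousands of independent microbial cultures from timed photographs of
    agar plates and compares parallel deletion-library screens (control
    versus query condition) to infer genetic interactions. This package
    fits logistic population-growth curves and calls interactions with
    Bayesian hierarchical models sampled by Metropolis-within-Gibbs MCMC:
    a separate growth model per screen (SHM), a fitness-level interaction
    model under Fisher's multiplicative model of genetic independence
    (IHM), and a joint one-stage model in which carrying capacity and
    growth rate provide evidence for interaction simultaneously (JHM).
    Interactions are flagged by the posterior mean of a per-gene Bernoulli
    indicator. A frequentist per-gene linear-model comparator with
    Benjamini-Hochberg correction, generative simulators for all three
    models, least-squares curve fitting, fitness measures (maximum
    doubling rate and doubling potential), and MCMC diagnostics are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda,
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
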