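Package: cellfate
Title: Markovian Cell-Fate Transition Dynamics, Bayesian Rate Estimation,
    and Stochastic Population Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cell-fate dynamics of cultured cell
    populations observed as daily counts of proliferating, differentiated,
    and dead cells. Implements a three-state continuous-time Markov
    transition model (linear ODE system with analytic eigen-solution,
    phase-portrait classification, and Malthusian growth rate), population
    heterogeneity and response metrics (Shannon entropy of fate fractions,
    initial and time-averaged fluxes, growth-factor response indices,
    effect sizes), Bayesian estimation of single-cell transition rates from
    population time courses by random-walk Metropolis-Hastings with a
    four-phase simulated-annealing schedule and gamma priors, an exact
    Gillespie simulator of the five-reaction fate scheme with model
    variants for parameter and initial-condition dispersal, Taylor
    power-law (mean-variance) analysis, and a study-shaped synthetic-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
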