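Package: twostepRL
Title: Simulation and Analysis of the Two-Stage Markov Decision Task with
    Hybrid Model-Free/Model-Based Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Behavioural", "Modelling Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative model of the two-stage sequential choice task
    (probabilistic first-stage transitions, Gaussian random-walk reward
    probabilities with reflecting boundaries), the seven-parameter hybrid
    model-free/model-based reinforcement-learning agent (SARSA temporal
    difference learning, model-based planning over the transition structure,
    softmax choice with perseveration), per-session maximum-likelihood
    parameter estimation with a parameter-recovery harness, stay-probability
    factorial statistics with model-free and model-based effect scores,
    one-way repeated-measures ANOVA with partial eta squared for
    within-subject intervention designs, and blood tryptophan/LNAA-ratio
    area-under-curve validation. Includes a synthetic-cohort generator
    emulating a 98-subject, three-intervention cross-over design and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
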