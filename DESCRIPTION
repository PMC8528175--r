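Package: numgroup
Title: Simulation and Analysis of the Connectedness Numerosity Illusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse two-alternative forced-choice
    numerosity discrimination experiments in which pairwise connecting dots
    induces an underestimation illusion whose strength depends on attention
    and autistic-like traits. Generates isolated and connected random-dot
    stimuli under geometric non-overlap constraints, simulates observers
    whose grouping probability and internal Weber noise vary with attentional
    load and Autistic Quotient score, drives trials with a QUEST Bayesian
    adaptive staircase, fits cumulative-Gaussian psychometric functions by
    maximum likelihood (PSE, JND, Weber fraction, percent bias), and provides
    group-level statistics: repeated-measures ANOVA with partial eta squared
    and BIC-approximate Bayes factors, Pearson correlations with default-prior
    Bayes factors, and the Jarque-Bera normality test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    tibble,
    dplyr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
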