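Package: killitox
Title: From Larval Killifish Behavior and Brain Expression to Cohort-Level Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking larval fish behavior assays and brain
    expression counts to population-relevant predictions. Provides synthetic
    generators for multi-state movement trajectories, feeding-assay events and
    negative-binomial count matrices; per-larva behavior endpoint extraction
    (distance, swimming bouts, turning angles, startle, feeding metrics); a
    three-state (slow/medium/fast) hidden Markov model of swimming with gamma
    step-length and von Mises turning-angle emissions fitted by Baum-Welch;
    Pos/Neg/NS trend calling across ordered treatment comparisons for both
    behavior endpoints (Bayesian two-arm comparison) and genes (negative
    binomial models at a 0.05 false discovery rate); trend-pattern concordance
    matching of genes and behaviors; and an individual-based bioenergetics
    simulator translating behavior-derived multipliers into cohort percent
    survival and growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    readr,
    ggplot2
Config/testthat/edition: 3
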