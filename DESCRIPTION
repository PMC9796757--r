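Package: lowbmm
Title: Bayesian Mallows Model with Unsupervised Item Selection for High-Dimensional Rank Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a lower-dimensional Bayesian Mallows model to complete rank
    data: only a small subset of the items is assumed to follow a Mallows
    distribution with the footrule distance around a latent consensus ranking,
    while the remaining items are treated as unranked noise. Inference is by a
    two-block Metropolis-Hastings sampler over the joint space of item subsets
    and consensus permutations, with leap-and-shift proposals for the consensus
    and symmetric swap proposals for the subset. Includes posterior summaries
    (selection frequencies, highest probability set, consensus estimate,
    top-probability selection), off-line tuning of the fixed scale parameter by
    pairwise-distance matching, synthetic rank-data generators (top-rank and
    rank-consistency processes, iterative swap-noise perturbation), evaluation
    metrics for simulation studies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
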