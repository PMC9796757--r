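# lowbmm

Bayesian Mallows modeling with unsupervised item selection for
high-dimensional rank data.

## The problem

Rank data with very many items arise naturally in transcriptomics: every
sample ranks all n genes by expression (rank 1 = most highly expressed).
When n is large it is unrealistic to assume a consensus ranking of *all*
items exists — typically only a small subset of items is consistently ranked
across assessors while the rest is noise. `lowbmm` fits a lower-dimensional
Bayesian Mallows model that simultaneously selects the relevant subset and
estimates its consensus ranking.

## Model

For complete rankings R ∈ 𝒫ₙ the footrule Mallows model is
P(R | α, ρ) ∝ exp{−(α/n) Σᵢ |Rᵢ − ρᵢ|}. The subset model assumes an unknown
set A\* of n\* items follows a Mallows distribution with consensus
ρ ∈ 𝒫ₙ\* and fixed scale α, while the remaining items are uniform noise;
with uniform priors the joint posterior is

P(ρ, A\* | R₁…R_N) ∝ exp{ −(α/n\*) Σⱼ Σ_{i∈A\*} |R_{ji} − ρ(i)| }.

Inference is by a two-block Metropolis–Hastings sampler (leap-and-shift
proposals for ρ with the exact proposal-mass correction; symmetric swap
proposals for A\*), implemented in C++. Posterior summaries (selection
frequencies, consensus estimate, top-probability selection), an off-line
distance-matching estimator of α, synthetic rank-data generators, and
evaluation metrics for simulation studies are included. See the methods
vignette (`vignettes/lowbmm-methods.Rmd`) for the full account.

## Worked example

Simulate top-rank data — 8 of 20 items carry a Mallows-distributed signal at
α = 3 across 50 assessors — then fit, summarize, and score against the truth:

```r
library(lowbmm)

sim  <- simulate_toprank(n = 20, n_star = 8, N = 50, alpha = 3, seed = 1)
fit  <- lowbmm(sim$rankings, n_star = 8, alpha = 3, iterations = 5000, seed = 2)
fit
#> Lower-dimensional Bayesian Mallows model fit
#>   items: 20  selected subset size: 8  alpha: 3
#>   kept samples: 4500 (1 chain, 5000 iterations, burn-in 500, thin 1)
#>   acceptance rates: rho 0.063, subset 0

summ <- posterior_summary(fit, top_k = 4, cutoff = 0.5)
summ
#> lowBMM posterior summary (4500 samples, n = 20, n_star = 8, HPS size k = 8)
#> # A tibble: 8 × 6
#>    item label  consensus_rank mean_rank selection_frequency top_k_probability
#>   <int> <chr>           <int>     <dbl>               <dbl>             <dbl>
#> 1     4 item4               1      1.30                   1                 1
#> 2     7 item7               2      1.70                   1                 1
#> 3     1 item1               3      3                      1                 1
#> 4     2 item2               4      4                      1                 1
#> 5    13 item13              5      5                      1                 0
#> 6    19 item19              6      6                      1                 0
#> 7    11 item11              7      7                      1                 0
#> 8    17 item17              8      8                      1                 0
#> top-probability selection (K = 4, c = 0.5): item1, item2, item4, item7

evaluate_selection(sim$truth, summ)
#> # A tibble: 1 × 5
#>   n_corr coverage d_norm d_tau d_recovery
#>    <int>    <dbl>  <dbl> <int>      <dbl>
#> 1      8        1      0     0          0
```

All eight planted items are recovered (`coverage = 1`) in their true order
(`d_tau = 0`, `d_recovery = 0`). Items 4 and 7 compete for the top two ranks
(mean posterior ranks 1.30 and 1.70) — the kind of rank uncertainty the
posterior is designed to expose. The zero subset-acceptance rate is typical
of strong-signal data: the chain sits on the dominant subset; with weaker
signal (smaller α or N) both acceptance rates move into the interior.
`tidy(fit)`, `glance(fit)` and `autoplot(fit)` give per-item tables, a
one-row run summary, and the marginal posterior heatmap; `estimate_alpha()`
tunes α from the data before fitting.

A command-line interface wrapping the same functions (subcommands
`simulate`, `fit`, `summarize`, `tune-alpha`, `evaluate`) is installed at
`system.file("scripts", "lowbmm.R", package = "lowbmm")`.

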