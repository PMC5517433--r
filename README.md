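# patchboot

Nonparametric bootstrap confidence intervals for functions of a network
degree distribution — the degree probabilities `f(k)` and the mean degree
`μ(G)` — computed from a **single, partially observed** graph, with no
assumption on the degree law and no knowledge of the network order.

`patchboot` is aimed at anyone who must report uncertainty for degree-based
summaries of a large network they can only sample: social and collaboration
networks, contact networks in epidemiology, biological interaction networks.
Point estimators for such summaries are plentiful; calibrated error bars are
not. The package implements a patchwork bootstrap: the network analogue of
the block bootstrap for time series and of re-tiling for spatial data.

## The method

Let `G_n` be the observed realization of an involution-invariant random
graph `G` with degree distribution `F = {f(k), k ≥ 0}`. The procedure has
two stages:

1. **Sampling.** Grow *patches* (ego networks) around `m` uniformly sampled
   *seeds* by a labeled snowball with multiple inclusions (LSMI): a
   breadth-first expansion for `d` waves in which no edge is ever traced
   twice, and a newly reached vertex is recorded once per distinct untraced
   edge leading to it. Seed degrees are observed exactly; non-seed vertices
   enter a patch along an edge, so they over-represent high degrees.

2. **Resampling.** Within the patches, resample `m` seeds uniformly with
   replacement, and resample the pooled non-seed records with probability
   proportional to `1/k` (the Horvitz–Thompson correction for unequal
   inclusion). Each bootstrap replicate yields

   ```
   f*(k) = ( |v*_s(k)| + (1 − p̂₀*) |v*_ns(k)| ) / ( |v*_s| + |v*_ns| ),  k ≥ 1
   f*(0) = p̂₀*,           μ* = Σ_k k f*(k)
   ```

   where `p̂₀*` is the proportion of zeros among resampled seeds. The
   100(1 − α)% interval is the Efron percentile interval of the `B`
   replicate values.

Patch size — the seed-wave combination `(m, d)` — governs a bias–variance
trade-off: seeds-only estimators are unbiased but noisy; waves add
information and shrink the bootstrap spread at the cost of bias. The
combination is chosen by cross-validation from **one** maximal snowball
sample: every combination of a grid is a prefix-and-truncation view of it,
each view's percentile interval is scored by the fraction of cheap
seeds-only proxy estimates it contains, and the combination closest to the
nominal level wins.

The package also provides the parametric degree laws used for validation
(zero-truncated Poisson, polylogarithmic `f(k) ∝ k^(−λ) e^(−k/θ)`),
synthetic graph generation with a prescribed degree sequence (configuration
model plus rewiring to a simple graph), the SRS competitor intervals (NCI,
the normal interval with finite-population correction; QCI, the SRS
resampling quantile interval), and a Monte Carlo harness that tabulates
empirical coverage and mean interval width per method and target.

## Worked example

```r
library(patchboot)
set.seed(1)

model <- degree_model("polylog", lambda = 0.1, theta = 2)
model_mean(model)
#> [1] 2.422483

g <- sample_network(model, 5000)
g
#> <simple_net> 5000 vertices, 6094 edges, mean degree 2.438

cv <- cross_validate(g, seed_wave_grid(c(20, 30, 40, 50), 1:3),
                     B = 500, target = "mean")
cv
#> <cv_report> target mean_degree, 12 combos, chosen m = 30 seeds, w = 1 waves
#>   95% CI (2.029, 2.856), proxy coverage 0.923
```

The chosen patch uses 30 seeds and one wave; its 95% interval for the mean
degree, (2.03, 2.86), contains the population value 2.42. The per-combination
table (`tidy(cv)`) shows the trade-off the selection arbitrates: deeper
patches give narrower intervals whose proxy coverage falls away from 0.95.

```r
srs <- srs_degrees(g, 50)
dplyr::bind_rows(
  nci(srs, n = g$n, k = 2, alpha = 0.05),
  qci(srs, k = 2, B = 500, alpha = 0.05)
)
#> # A tibble: 2 × 8
#>   method target level  lower upper     M     n     B
#> 1 NCI    f(2)    0.95 0.0579 0.262    50  5000    NA
#> 2 QCI    f(2)    0.95 0.08   0.28     50    NA   500
```

Both competitor intervals for `f(2)` are ~0.20 wide; the patchwork interval
for the same target is typically a third narrower at comparable or better
coverage (see the coverage study below).

A coverage experiment end to end:

```r
cfg <- experiment_config(
  degree_model("ztp", lambda = 2), n = 2000,
  methods = c("FPB", "NCI"), targets = list(2, 3),
  grid = seed_wave_grid(c(20, 30, 40, 50), 1:3),
  B = 200, M = 50, mc_reps = 200, rng_seed = 42
)
run_experiment(cfg)
#> # A tibble: 4 × 9
#>   model      n method target truth coverage mean_width mc_reps mc_se
#> 1 ztp(2)  2000 FPB    f(2)   0.313     90        0.151     200  2.12
#> 2 ztp(2)  2000 FPB    f(3)   0.209     94        0.132     200  1.68
#> 3 ztp(2)  2000 NCI    f(2)   0.313     91        0.253     200  2.02
#> 4 ztp(2)  2000 NCI    f(3)   0.209     94.5      0.219     200  1.61
```

Coverage is the percentage of repetitions whose interval contained the
population value; `mean_width` is the sharpness. The patchwork intervals
are ~40% narrower than the normal SRS intervals at comparable coverage.

A command-line front end over the same functions lives at
`inst/cli/patchboot.R` (subcommands `generate`, `lsmi`, `boot`, `cv`,
`compare`, `simulate`).

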