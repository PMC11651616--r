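# colonyidle

Why do social-insect colonies carry so many idle workers? `colonyidle`
implements a cost–benefit simulation exploring one answer: when individual
worker performance is **random and uncontrollable**, a colony can maximize
its efficiency by producing many workers, activating only the
best-performing fraction, and leaving the rest inactive. The package is
aimed at behavioural ecologists and modellers of collective behaviour who
want to reproduce, probe or extend that result.

## The model

A colony of $N$ workers pays a production cost $c_p$ per worker and a
lifetime maintenance cost $\delta\,c_p$ per **active** worker, discounted
by $\beta \in [0,1]$ for inactive workers. With $k$ workers active,

$$C(k) \;=\; c_p N \;+\; \delta\, c_p\,\bigl(k + \beta\,(N-k)\bigr).$$

Worker performances $x_1,\dots,x_N \in [0,1]$ are drawn from one of five
distributions (truncated normal, truncated bimodal mixture, uniform, and
left/right-skewed power transforms $u^{1/s}$, $1-u^{1/s}$ of a uniform).
The $k$ best performers are activated, so colony performance is the top-$k$
sum $P(k)=\sum_{(i)\le k} x_{(i)}$, and colony efficiency is $P(k)/C(k)$
(or, optionally, $P(k)-C(k)$), normalized by its all-active value. Sweeping
$\beta$ (0.1–1 by 0.05) and $\delta$ (0–10 by 0.1) over 1000 Monte-Carlo
replicates yields a heat map of the optimal active fraction $k^*/N$.

## A worked example

```r
library(colonyidle)

cfg <- sweep_config(dist_spec("right_skew"), n_workers = 500)  # 1000 replicates
samples <- run_replicates(cfg)

curve <- aggregate_curve(samples, beta = 0.2, delta = 2, cfg)
curve
#> # A tibble: 99 × 6
#>    beta delta     k active_fraction mean_normalized_efficiency
#>   <dbl> <dbl> <int>           <dbl>                      <dbl>
#> 1   0.2     2    10            0.02                      0.145
#> 2   0.2     2    15            0.03                      0.206
#> 3   0.2     2    20            0.04                      0.262
#> 4   0.2     2    25            0.05                      0.314
#> # ℹ 95 more rows

optimal_active_fraction(curve)
#> [1] 0.6
```

With right-skewed performance (most workers poor, a few excellent),
maintenance twice the production cost ($\delta = 2$) and idle workers
cheap to keep ($\beta = 0.2$), efficiency peaks when only 60% of the
colony works: the mean normalized curve rises from 0.145 at 2% activity to
its maximum at 0.6 and falls back to 1 (the all-active reference) at
fraction 1. The full parameter sweep takes a few seconds:

```r
res <- run_sweep(cfg)
res
#> <sweep_result> right_skew N = 500, ratio mode, 1000 replicates
#>   1919 (beta, delta) cells; optimal active fraction in [0.34, 1]

glance(res)
#> # A tibble: 1 × 8
#>   distribution n_workers mode  n_replicates n_cells min_optimal_fraction …
#> 1 right_skew         500 ratio         1000    1919                 0.34 …

autoplot(res)          # (beta, delta) heat map of the optimal fraction
tidy(res)              # one row per grid cell
write_heatmap_csv(res, "heatmap.csv")
```

Somewhere on the grid it pays to idle two thirds of the colony
(`min_optimal_fraction` 0.34); at $\beta = 1$ or $\delta = 0$ activity is
free or savings impossible, and every worker should work.

A command-line driver wraps the same functions
(`inst/cli/colonysim.R`): subcommands `sample`, `curve`, `sweep`,
`figure1`, `s1`, `s2`, each writing CSVs plus a JSON manifest from which
`rerun_manifest()` reproduces the outputs byte for byte. YAML configs are
supported via `load_config()`.

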