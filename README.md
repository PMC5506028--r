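# tissuefail

Simulation and analysis of **systemic aging in engineered tissue
constructs** — an "aging in a dish" pipeline. The package asks how
microscopic cell failure becomes macroscopic tissue death: if cells are
independent, a tissue's population should decay exponentially,
`n(t) = n0 e^(-mt)`, with a constant per-capita mortality rate
`m = -(Δn/n)(1/Δt)`; if cells depend on one another (neighbor support,
secreted cooperative factors), failures beget failures, `m` rises as the
population thins, and the tissue collapses in a terminal cascade. Density
is the experimental dial: fibroblasts fixed in a non-degradable 5-µL,
100-µm-thick hydrogel at 1e3 ("1 K"), 1e4 ("10 K") or 1e5 ("100 K") cells
per construct cannot move or divide, so the encapsulation density alone
sets how strongly they interact.

The package is aimed at quantitative biologists and modellers who want a
tested, reproducible in-silico version of this experimental programme:

- **`interdependence model`** — a stochastic agent-based simulator:
  uniform cell placement in the slab, a fixed-radius interaction graph
  (grid-accelerated, exact), per-day intrinsic failure with hazard
  `1-(1-dσ)^exp(-βs)` modulated by support `s = c(f + w·G)` (functional
  neighbor fraction `f`, shared-medium factor `G`, reception competence
  `c`), synchronous threshold cascades, optional repair, and
  conditioned-media transfer between constructs.
- **measurement emulator** — the daily dead-cell staining protocol:
  3 z-stacks at random disjoint positions covering 1/8 of the gel each,
  10 optical slices, middle-slice counts for dense tissues and maximum
  projections for sparse ones, detection gain and count noise.
- **counting pipeline** — the per-gel dead-cell estimator (average ×
  slices × 8), affine calibration, cumulative live-cell bookkeeping,
  live-percentage series and the 98%-dead lifetime call.
- **mortality analysis** — `m(t)`, the exponential null fit, bootstrap
  classification of the `m(n)` trend (cooperative / competitive /
  non-interacting), probability-of-death and normalized-time curves,
  Student's t group comparisons.
- **experiments** — density sweeps, oxidative-stress arms, and the
  conditioned-media transfer matrix that discriminates two aging
  hypotheses: aged cells stop *producing* cooperative factors, or stop
  being able to *receive* them.

## Worked example

```r
library(tissuefail)

estimated_spacing(5, 1e5)
#> Estimated cell-cell spacing: 36.8 um (reported 35 um) for 100000 cells in 5 uL

sweep <- run_density_sweep(densities = c("1K", "100K"), replicates = 3, seed = 7)
sweep$summary
#>   density age_class mean_lifetime_d sd_lifetime_d n n_censored
#> 1    100K  pre_aged        4.666667     0.5773503 3          0
#> 2    100K     young       15.333333     1.1547005 3          0
#> 3      1K  pre_aged        5.666667     0.5773503 3          0
#> 4      1K     young        6.333333     0.5773503 3          1
sweep$tests
#>   density mean_young mean_pre_aged         t            p significant
#> 1      1K   6.333333      5.666667  1.414214 0.2301996411       FALSE
#> 2    100K  15.333333      4.666667 14.310835 0.0001385112        TRUE
table(sweep$trend_labels$density, sweep$trend_labels$label)
#>        cooperative non_interacting
#>   100K           3               0
#>   1K             0               6
```

Reading this output: at 100 K the young tissues live ~15 days versus ~5
for pre-aged ones (significant at p < 0.05), and every replicate's
mortality rate *rises* as the population thins (`cooperative`); at 1 K the
young/pre-aged difference is not significant and the rate is statistically
constant (`non_interacting`) — cellular aging only matters where cells are
close enough to interact. Each number is computed through the full
pipeline: simulate → stain/image → count → analyze.

`run_media_experiment()` and `evaluate_hypotheses()` reproduce the
conditioned-media discrimination (transfer from 100 K donors conditioned
2 days; daily refresh; paired-seed controls on fresh media): under
reception loss the aged tissues are not rescued by young conditioned media
while young sparse tissues are rescued by young *and* by aged conditioned
media; under production loss the pattern breaks.

See `vignettes/aging-in-a-dish.Rmd` for the model, the default parameters
and the analysis conventions.

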