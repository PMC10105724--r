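# somkin

Decomposition kinetics of soil organic matter (SOM), from laboratory
incubation curves to global parameter maps.

Earth system models describe SOM turnover with a handful of conceptual pools
(fast, slow, passive), each decaying by first-order kinetics at a reference
rate `k_ref` that is usually taken as a global constant. Laboratory
incubations tell a different story: fitted `k_ref` values span five orders of
magnitude across soils, and that variation is predictable from
edaphic-climatic conditions. `somkin` implements the full analysis chain a
synthesis of such incubation data needs:

1. **Kinetics fitting** — constrained nonlinear least squares for 1/2/3-pool
   first-order models on cumulative CO₂-C release (or instantaneous flux),
2. **Dataset summarization** — schema-validated compiled tables, pool-class
   comparisons (Kruskal–Wallis), reference-model reality checks,
3. **Predictive modelling** — MLR / random forest / gradient boosting of
   eight kinetics parameters from eleven covariates, with recursive feature
   elimination, repeated 10-fold CV, grid search and AIC-based selection,
4. **Global mapping** — applying trained models over gridded covariates, with
   relative-uncertainty layers (pH percentile propagation and RF per-tree
   spread) and latitudinal profiles,
5. **Synthetic data** — a seeded generator (Gaussian-copula covariates with
   the observed rank-correlation structure, known covariate→parameter maps,
   noisy incubation curves, gridded fields) so every stage is testable
   without downloads.

It is intended for soil biogeochemists compiling incubation syntheses and for
modellers who need spatially explicit `k_ref` priors.

## The model

The substrate remaining across `n` parallel pools at time `t` (days) is

    S(t) = S(0) · Σᵢ fᵢ · exp(−kᵢ t),      Σᵢ fᵢ = 1

with pool fractions `fᵢ ∈ [0, 1]` and rates `k₁ > k₂ > k₃ > 0` (d⁻¹).
Cumulative release and instantaneous flux follow as

    R_cum(t) = S(0) · (1 − Σᵢ fᵢ e^(−kᵢ t)),
    R(t)     = S(0) · Σᵢ kᵢ fᵢ e^(−kᵢ t).

Fitting minimizes the residual sum of squares of `R_cum` with
Levenberg–Marquardt iterations in a transformed space (ordered log-rates via
softplus gaps, stick-breaking fractions) so the constraints can never be
violated, with a deterministic multi-start protocol plus an
exponential-peeling data-driven start.

Model evaluation uses the coefficient of determination, the concordance
correlation coefficient `ρ_c`, RMSE, RMSE normalized by the interquartile
range of the observations, and `AIC = n·ln(SSE/n) + 2p`.

## Worked example

Fit a two-pool model to a noisy synthetic incubation curve generated from
known parameters (f = 0.2/0.8, k = 0.05/0.005 d⁻¹):

```r
library(somkin)
truth <- pool_kinetics(f = c(0.2, 0.8), k = c(0.05, 0.005), S0 = 1)
ser   <- gen_incubation_series(truth, noise_frac = 0.02, seed = 42)
fit   <- fit_first_order(ser, n_pools = 2, S0 = 1)
fit
#> first-order fit (2 pools, target = cumulative): RSS = 1.028e-05, R2 = 1.0000
#> 2-pool first-order kinetics (S0 = 1 mg C g^-1)
#>   pool         f         k_d
#> 1    1 0.1948942 0.051320558
#> 2    2 0.8051058 0.005014815
```

With 2% increment noise the fast pool is recovered to within ~3% and the slow
pool to within ~0.3% — the fractions and rates are read straight off
`fit$params`, and `fit$flags` would warn if the slowest pool were barely
expressed within the incubation window.

Summarize a compiled-style table (here the 859-record synthetic analogue) and
compare the pool classes:

```r
tab <- gen_kinetics_table(859, seed = 1)
cmp <- pool_comparison(tab)
subset(cmp$summary, parameter %in% c("k1", "k2", "k3"))[, 1:4]
#>   model_type parameter   n   median
#> 1         M2        k1 344 1.26e-01
#> 2         M2        k2 344 1.20e-03
#> 5         M3        k1 515 3.07e-02
#> 6         M3        k2 515 7.09e-04
#> 7         M3        k3 515 1.13e-05
```

The medians (in d⁻¹) separate the pool classes by roughly one and a half
orders of magnitude per step; `cmp$kw` carries the Kruskal–Wallis tests
between the two- and three-pool classes and `cmp$reference` checks the ANIMO,
DAISY, CLMcn and DAYCENT constants against the 50% intervals.

Train predictors and map a parameter with uncertainty:

```r
m3  <- tab[tab$model_type == "M3", ]
rf  <- train_model(m3, "k3", method = "rf", seed = 1)
variable_importance(rf)          # percent, sums to 100; pH dominates k3
ras <- gen_rasters(30, 60, seed = 1)
pg  <- predict_grid(rf, ras)     # lat/lon grid of predicted k3
un  <- structure_uncertainty(rf, ras)   # ReUn from the 100-tree spread
latitudinal_profile(pg, band = 0.5)     # per-band mean and 90% interval
```

An end-to-end run from one config is `run_pipeline(list(out_dir = "out",
stages = c("simulate", "summarize", "train", "map", "profile")))`.

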