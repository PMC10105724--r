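---
title: "Methods: multi-pool SOM decomposition kinetics, prediction and mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-pool SOM decomposition kinetics, prediction and mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somkin)
```

## The kinetic model and its assumptions

Laboratory incubations measure CO₂-C release from a soil sample held at
fixed temperature and moisture. `somkin` describes the substrate as 1–3
parallel pools, each decaying by first-order kinetics:

$$S(t) = S(0)\sum_{i=1}^{n} f_i e^{-k_i t}, \qquad \sum_i f_i = 1,$$

with cumulative release $R_{cum}(t) = S(0)(1 - \sum_i f_i e^{-k_i t})$ and
flux $R(t) = S(0)\sum_i k_i f_i e^{-k_i t}$. The assumptions are the usual
ones: pools are independent, rates are constant over the incubation (the
fitted $k_i$ are *reference* rates at the laboratory condition, not field
rates), and pool membership is fixed at $t = 0$. Temperature/moisture rate
modifiers and microbial-explicit formulations are deliberately out of scope —
this package characterizes the reference rates that such modifiers act on.

Pools are always stored fast-to-slow ($k_1 > k_2 > k_3$). This is a pure
labelling convention, but enforcing it everywhere makes fits invariant to
pool permutation and makes "fast/slow/passive" unambiguous in tables.

## Fitting

`fit_first_order()` minimizes the RSS of modeled vs observed **cumulative**
release by default. Compiled syntheses mostly derive their parameters from
cumulative CO₂ curves, so that is the default target; `target = "flux"`
fits the instantaneous rate instead for sources that report fluxes.

Constraints are removed by reparameterisation rather than by bounds:

* rates: $\log k_1 = a_1$, $\log k_i = \log k_{i-1} - \mathrm{softplus}(a_i)$,
  which guarantees a strictly descending rate ladder for any real $a$;
* fractions: logistic stick-breaking, which keeps $f$ on the simplex;
* $S(0)$: fixed when supplied (the usual case when a SOC-derived stock is
  measured), otherwise fitted as $e^{\theta}$.

The unconstrained problem is solved with Levenberg–Marquardt iterations
(`minpack.lm::nls.lm`, relative-RSS tolerance $10^{-13}$, up to 500
iterations), which adds damping to the plain Gauss–Newton step and is far
more robust on the ill-conditioned late-time plateau of multi-exponential
curves. Three start strategies are combined:

1. an **exponential-peeling** start: the remaining substrate is log-linear in
   its slowest component at late times, so the slowest pool is estimated from
   the tail by linear regression, subtracted, and the procedure repeated
   toward the fastest pool;
2. a deterministic **multi-start grid**: descending rate combinations from a
   half-decade log grid on $[10^{-6}, 1]$ d⁻¹ (24 starts by default, ordering
   seeded), with fraction starts cycling simplex corners and the centroid;
3. a **polish restart** of Levenberg–Marquardt from the incumbent best, which
   resets the damping and escapes shallow plateaus.

Degenerate inputs (no release, non-monotone cumulative) are fitted anyway but
flagged `degenerate_input`. A second flag, `slow_pool_unidentifiable`, is
raised when $\mathrm{duration} \times k_{slowest} < 0.05$: below that the
slowest pool has expressed less than ~5% of its mass within the window and is
numerically indistinguishable from inert mass — fits in that regime can place
$k_{slowest}$ anywhere between its true value and zero while changing the
RSS at the $10^{-12}$ level. The round-trip guarantees (0.1% parameter
recovery on noiseless curves) therefore apply to the identifiable regime the
flag delimits.

## Evaluation metrics

`evaluate()` is the single implementation of the evaluation formulas used by
every stage (fit diagnostics, CV scores, AIC ranking):

* $R^2 = 1 - SSE/\sum(y_{obs}-\bar y_{obs})^2$ — which is exactly 0 for the
  constant-mean predictor and can be negative out of sample;
* the concordance correlation coefficient in its **population form**,
  $\rho_c = 2 S_{xy} / [n(\bar y_{sim}-\bar y_{obs})^2 + S_{xx} + S_{yy}]$
  with raw centered sums (no $n-1$ correction) — deliberately not replaced by
  a sample-variance variant, so hand-computable cases like the shifted pair
  $(1{:}4, 2{:}5) \mapsto 10/14$ hold exactly;
* RMSE, and RMSEn = RMSE / IQR of the observations;
* $AIC = n\ln(SSE/n) + 2p$ with $p$ = number of explanatory variables. This
  is the only AIC used for model comparison — not a likelihood-based variant —
  so AIC differences are directly interpretable in terms of SSE and $p$.

All quantiles (RMSEn's quartiles, summary intervals, ReUn bounds,
latitudinal bands) use linear interpolation of order statistics (R's type 7),
fixed once and documented; "90% interval" always means the central 5–95%
range and "50%" the quartile range.

Kruskal–Wallis tests and Spearman matrices wrap the standard
tie-corrected implementations; constant columns yield flagged `NA`
correlations rather than silent zeros.

## The compiled-table schema

One row is one fitted incubation record: coordinates (WGS84 decimal
degrees), the eleven covariates (MAP, MAT, Sand, Clay, pH, SOC, MBC, Elev,
Slope, NDVI, IncT), incubation metadata, the model class (M1/M2/M3), the
fractions and rates, and fit diagnostics. Conventions:

* missing values are empty cells, never 0 or −999;
* rates are stored in d⁻¹; per-year rates are divided by 365 on read, and an
  unknown unit is a hard error rather than a guess;
* the derivable fraction is recomputed on load (f2 = 1 − f1 for M2,
  f3 = 1 − f1 − f2 for M3) — sources often omit it;
* invalid rows go to a reject report with row numbers and reasons; they are
  never silently dropped;
* texture must sum to 100 within 2 (source rounding).

Gap-filling from gridded layers samples the nearest cell center and flags
every filled entry (`<var>_filled`), so provenance survives into modelling.

## Predictive modelling

Eight parameters are modeled (M2: k1, k2, f1; M3: k1, k2, k3, f1, f2) from
the eleven covariates. Design choices, with rationale:

* **Target transform.** Rates span five orders of magnitude, so all `k`
  targets are modeled as $\log_{10} k$ and inverted on prediction; fractions
  are modeled raw on $[0,1]$. The transform travels with the model object.
* **Partition.** 75/25 train/test, stratified on five response-quantile bins
  so both tails are represented on both sides; too-small data fall back to a
  simple random split with a warning.
* **Cross-validation.** Repeated 10-fold (3 repeats) by default; scores are
  the mean per-fold $R^2$.
* **Grids.** GBM (xgboost backend): trees {10, 50, 100, 150, 200} × depth
  1–7 × shrinkage {0.01, 0.1}, minimum node size fixed at 10 — the tree-count
  axis is scored from one maximal-tree fit per fold via nested prediction.
  RF: 100 trees, mtry from 2 to p−1. MLR has no grid.
* **RFE.** Features are ranked once by importance on the full data; nested
  subsets of every size are scored by k-fold CV; among subsets within 0.01
  CV-$R^2$ of the best, the smallest wins (deterministic, parsimonious,
  AIC-spirited).
* **Repeats.** `repeat_and_select()` reruns the whole partition+train cycle
  with fresh seeds (the reference protocol uses 100 repeats) and keeps the
  best test-$R^2$ run, retaining all per-run metrics.
* **Importance.** RF: out-of-bag permutation importance; GBM: gain; MLR:
  absolute standardized coefficients; all floored at zero and normalized to
  sum to 100%.
* **Partial dependence.** Clamp-and-average over the data, reported on a
  0–1 normalized feature axis; available on the modeling scale (where
  additive structure is visible) or the natural scale.

Both train-side and CV-resampled scores are recorded and labelled
(`metrics_train`, `cv_r2`, `metrics_test`), since syntheses are often unclear
about which of the two a reported $R^2$ is.

## Gridded prediction and uncertainty

Covariate layers live in a lightweight lat/lon container (`grid_raster`,
rows north→south, values at cell centers) with a self-describing plain-text
exchange format. Bilinear resampling interpolates between cell centers; any
missing contributing cell makes the output cell missing, and target centers
outside the source hull clamp to the border (documented, visible only in the
outermost half-cell). The default analysis extent is 60°S–90°N, matching the
coverage of global soil-property products. The working resolution is a
configuration value — analyses in the tests run on coarse grids (e.g. 30×60
cells); nothing is hard-coded to 1 km.

Relative uncertainty is $ReUn = \mathrm{Width}_{90\%CI} / \mathrm{Mean}$,
computed two ways:

* **input uncertainty**: the width is the absolute difference between
  predictions under the 95th- and 5th-percentile pH layers (a model whose
  subset excludes pH has ReUn ≡ 0);
* **structure uncertainty**: per-cell empirical 5–95% quantiles over the RF's
  individual-tree predictions, on the natural parameter scale, against the
  tree-ensemble mean. The quantile estimator (type 7 on the 100 tree values)
  is a documented choice; fewer than 10 trees triggers a warning.

Cells with non-positive mean prediction are masked and counted — never
silently clipped. ReUn is scale-invariant by construction. Latitudinal
profiles aggregate 0.5° bands by default (unweighted; `area_weighted = TRUE`
applies cos-latitude weights), reporting empty bands as missing.

## The synthetic world

The generator produces every input the pipeline consumes, as a pure function
of (config, seed):

* **Covariates** via a Gaussian copula: rank correlations are imposed on the
  copula scale ($r = 2\sin(\pi\rho_S/6)$), so the monotone marginal
  transforms preserve them exactly. The configured structure is the two
  strong empirical correlations — $\rho_S$(MAP, MAT) = 0.822 and
  $\rho_S$(Elev, Slope) = −0.775 — with all other pairs near zero; texture is
  built on the simplex so Sand + Silt + Clay = 100 exactly. A non-PSD
  correlation matrix would be repaired to the nearest PSD matrix with a
  warning.
* **Parameters** from a known map: $\log_{10} k$ = intercept + 0.8 × a smooth
  hump of the dominant covariate + 0.25 × a linear trend of a secondary one +
  Gaussian noise (SD 0.15, truncated at 2.5 SD). Intercepts sit at the
  compiled-data medians (M2: 0.12 and 1.1×10⁻³; M3: 0.029, 6.8×10⁻⁴ and
  1.06×10⁻⁵ d⁻¹), so generated medians fall inside the compiled 90% intervals
  by construction. The default dominance mirrors the empirical importance
  pattern: Sand→k1, MAP→M3-k2, pH→the slowest pool. The amplitude/noise
  ratio gives a theoretical $R^2 \approx 0.75$, placing attainable model
  skill inside the empirically reported test range (0.52–0.77); this
  calibration was fixed at design time. Rare noise-tail rows that would
  break the rate ordering are repaired (slower rate shrunk) and counted.
  Fractions come from a logistic/softmax map with mild NDVI and SOC trends.
* **Incubation curves**: exact cumulative curves with truncated-Gaussian
  noise on the *increments* (SD = 2% of the increment by default), then
  re-cumulated — so synthetic curves are monotone like real chamber data.
  Sampling defaults to 60 log-spaced points over 0.25–365 d, denser early
  where the fast pool dominates.
* **Rasters**: per covariate a sinusoidal latitudinal gradient with a seeded
  phase plus smoothed spatial noise, pushed through the same marginal ranges
  as the tabular generator; pH ships with 5%/95% layers at mean ∓ 0.5 units.
  `sites_from_rasters()` samples site records off the grids, so table and
  raster paths share one generator.

What the synthetic world does **not** emulate — and hence what passing tests
do not show about real data: the spatial autocorrelation of real climate and
soil products; the geographic sampling bias of compiled records (real sites
cluster at 25–50°N); reporting heterogeneity across source studies (different
fitting targets, durations, digitization error); and the true noise structure
of incubation measurements, which is unreported and here an explicit
assumption. The generator demonstrates that the pipeline recovers structure
it is pointed at, not that any particular real-world covariate dominates.

## Problem sizes and numerical choices

The shipped tests run on deliberately compact instances: tables of 150–1334
records, grids of 10×20 to 30×60 cells, RF with 40–100 trees, CV with 2–5
folds where the full 10×3 design is not itself under test, and 20-seed
replication for the stochastic benchmark claims. The full-size defaults
(10-fold ×3 CV, the complete GBM lattice, 100 repeats) remain the exported
defaults. Other fixed numerics: fraction simplex tolerance 10⁻⁹ at
construction and 10⁻⁶ on ingested tables; LM tolerances 10⁻¹³; tie threshold
0.01 CV-$R^2$ in RFE; identifiability threshold 0.05 on duration × k.

## Known limitations

* The fitter assumes a single measured series per record; replicate curves
  must be averaged (or fitted separately) upstream.
* AIC compares models sharing one observation set and one modeling scale; it
  cannot compare a log-scale rate model with a raw-scale fraction model.
* Structure uncertainty is only available for RF (per-tree access); GBM's
  staged predictions are not an ensemble in the same sense.
* The grid container is geographic lat/lon only — no projections, no GeoTIFF;
  the plain-text exchange format is meant for interoperability at the scale
  of analysis grids, not 1-km global products.
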