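---
title: "Dissecting genotype-by-environment interaction with temporal environmental windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genotype-by-environment interaction with temporal environmental windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxewindows)
```

## The problem

Multi-environment trials phenotype a panel of genotypes (here, an
inbred-line panel of the kind used in cotton breeding) in many
year-by-site environments. Trait variation then mixes genotype main
effects, environment main effects, and genotype-by-environment (G×E)
interaction. Two questions drive this package:

1. **Which environmental factors, acting during which days of the
   season, drive the environmental component?** Daily weather gives
   eight base variables (`tmax`, `tmin`, `tmean`, `pcp`, `dh`,
   `rhmean`, `radn`, `wsmean`) and five derived indices — growing degree
   days (GDD, base 10 °C), diurnal temperature range (DTR),
   precipitation per diurnal range (PRDTR), photothermal quotient
   (PTQ), and photothermal time (PTT) — thirteen candidate factors,
   each a 150-day series per environment.
2. **Does knowing those critical windows improve cross-environment
   prediction?** If a model trained in twelve environments must predict
   two unseen ones, a feature set reduced to the causal windows should
   generalise at least as well as the full grid.

The package implements the full chain: variance decomposition
(fixed-effects ANOVA, Finlay–Wilkinson joint regression, GGE SVD), an
exhaustive sliding-window correlation scan, random-forest attribution
profiling with TreeSHAP, key-window selection, and leave-environments-out
validation — plus a synthetic-data generator with planted ground truth
that makes every stage testable.

## Variance decomposition

`anova_decompose()` fits the fixed-effects model
`y ~ Genotype + ENVs + Rep + Genotype:ENVs` with sequential (type I)
sums of squares in that order, and reports each stratum's share of the
total sum of squares as a percentage. In a balanced trial the sequential
sums of squares coincide with the classical main-effect and interaction
sums of squares and are exactly additive; unbalanced data are accepted
with a warning, with the documented order defining the decomposition.
Rep enters as a crossed main effect (one Rep stratum with
`n_reps - 1` degrees of freedom), not nested in environment. Variance
shares are SS ratios, not REML variance components — the convention that
matches how such trial tables are usually printed, and the one exactly
recomputable from a published table's SS column.

`fw_regression()` computes Finlay–Wilkinson plasticity: environment
effects `E_j` are environment means minus the grand mean of the cell
means (so they sum to zero), and each genotype's cell means are
regressed on `E_j` by OLS. The slope (`1 + b_i`) measures plasticity and
averages exactly 1 on complete data.

`gge_biplot()` centers each environment's column of the
genotype-by-environment mean table (removing `mu + beta_j`) and factors
the remainder by SVD, `Y_ij = mu + beta_j + sum_k lambda_k gamma_ik
delta_jk`. Axis `k` explains `lambda_k^2 / sum(lambda^2)` of the
genotype-plus-interaction variation. Scores use the symmetric scaling
(`sqrt(lambda)` absorbed into each side); no published convention is
universal here, and the symmetric choice treats genotype and environment
markers even-handedly in a biplot.

## The sliding-window scan

`scan_windows()` is an exhaustive grid search: for every factor, every
start day 1–145 and every duration 5–150 days (ends bounded only by the
season), the per-environment window *mean* is correlated across
environments with the per-environment population phenotype mean. For a
150-day season that is 10,730 windows per factor. The window statistic
is the arithmetic mean rather than the sum so that windows of different
lengths are comparable; cumulative readings (total GDD in a window) are
`mean × length`. The p-value uses the exact t transform
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom, two-sided,
with `-log10(p)` reported; a permutation option exists for verification.
At `|r| = 1` the p-value is floored at the smallest positive double so
`-log10(p)` stays finite. Ranking is by `|r|`, ties broken by larger
`-log10(p)`, then earlier start, then shorter duration — a deterministic
convention so reruns agree.

No multiple-testing correction is applied across the ~139k windows: the
scan is exploratory, and its output is a ranked map, not a set of
significance claims.

## Random-forest attribution and key windows

`fit_rf_for_trait()` trains a regression forest (default 500 trees,
squared-error/variance split criterion) on genotype-by-environment
samples. Features are the dense stride-1 grid of 5-day window means
(146 windows × 13 factors = 1,898 columns for a 150-day season) plus
genotype principal components retained to >90% cumulative variance. PC
covariates absorb genotype main effects so window importance reflects
the environmental signal; they are profiled separately and are never
eligible as key windows. `mtry` defaults to `floor(p/3)`, the classic
regression-forest convention.

Because no TreeSHAP implementation exists in this package's R dependency
set, the package carries its own: exact path-dependent TreeSHAP in C++
(`src/treeshap.cpp`), operating on the exported tree structures with
per-node covers recomputed by routing the training data through each
tree. Local accuracy — base value plus attributions equals the forest
prediction for every sample — is asserted in the tests, not assumed.

`select_key_windows()` mirrors the usual post-processing: both the
impurity-importance profile and the mean-|SHAP| profile are smoothed
along the window sequence with a centered 5-window moving average
(edges shrink to the available neighbours; never zero-padded), and a
window is significant when it reaches 10% of the *global* maximum of
each smoothed profile. Two open conventions had to be fixed:

* **AND-combination.** A window must clear the 10% threshold on both
  importance and SHAP. The AND rule is the conservative reading of
  "selected by importance and SHAP values"; `combine = "or"` and
  single-criterion modes are available.
* **Global threshold.** The 10%-of-maximum cut is taken across all
  window features, not per factor, so a factor with a uniformly weak
  profile contributes no windows at all.

Significant windows of the same factor that overlap or touch merge into
one period (minimum start, maximum end), ranked by peak smoothed SHAP.

## Cross-environment validation

`make_env_folds()` randomly partitions the environments into 7 folds
(2 of 14 held out per fold by default); `cross_env_evaluate()` trains on
the remaining environments and predicts every held-out sample, pooling
all held-out predictions before computing PCC, R² (about the pooled
observed mean) and MSE — pooled rather than per-fold-averaged metrics,
matching the "combine predictions, then score" convention. Samples are
rep-averaged genotype-by-environment observations by default, since
replicates carry no distinguishing features. Learners sit behind a
fit/predict registry: random forest (ranger), gradient boosting
(xgboost, if installed), SVR (e1071), elastic net (glmnet, lambda by CV
on the training folds), a Bayesian ridge written in-package
(MacKay/Tipping evidence maximisation — the standard
marginal-likelihood ridge), and a training-mean baseline. LightGBM is
registered only when an R package of that name is available.
`compare_feature_sets()` reruns the CV with the full grid and with a
selected subset and reports both metric sets, deltas, and the selection
ratio.

## The synthetic generator and what it emulates

`simulate_gxe()` builds a trial with known truth:

* **Weather.** Each environment draws a 150-day season from a climate
  archetype: `arid` (high radiation peaking near 28 MJ m⁻² day⁻¹,
  relative humidity near 50%, precipitation 0.4–1.2 mm day⁻¹, weak
  winds with a spring gust), `semi_arid` (2.0–5.1 mm day⁻¹,
  intermediate radiation and humidity, persistent >2 m s⁻¹ winds), and
  `humid` (4.8–7.2 mm day⁻¹, radiation under 20 MJ m⁻² day⁻¹, humidity
  near 75%). Series are a seasonal sinusoid plus stationary AR(1)
  day-to-day noise, truncated at physical bounds; `tmin ≤ tmean ≤ tmax`
  holds by construction. The default mix is 4 arid + 6 semi-arid +
  4 humid = 14 environments.
* **Genotypes.** 250 inbred lines × 500 biallelic homozygous markers in
  correlated blocks, so a low-dimensional PC representation exists.
* **Phenotypes.** `y_ijk = mu + g_i + (1 + b_i) E_j + rep_jk +
  eps_ijk`, with `E_j` the sum over planted windows of
  `effect × (window mean, centered across environments)`. Genotype
  effects and slope deviations are drawn normal and exactly centered, so
  `mu` is the grand mean and the mean FW slope is exactly 1. Defaults:
  3 replicates, `g_sd = 0.35`, `slope_sd = 0.2`, `rep_sd = 0.05`,
  `noise_sd = 0.4` (boll-weight-like units around `mu = 5.8` g), and a
  default planted truth of a positive radiation window at days 104–110
  and a negative precipitation window at days 50–56.

The generator does **not** emulate spatial correlation between
environments, missing data, real within-site weather statistics beyond
the configured ranges, or nonlinear dose-response; passing tests
therefore demonstrate that the machinery recovers planted *linear*
window signals under realistic noise, not that any particular real
dataset contains such signals.

## Identifiability and the design of the recovery experiments

Two properties of the feature geometry shaped the recovery tests, and
they are worth knowing before interpreting any real analysis:

* **Derived-index collinearity.** GDD is an affine function of `tmean`,
  PTT couples GDD with sunshine, PTQ couples radiation with GDD, PRDTR
  couples precipitation with DTR. Window features within such a family
  are nearly (sometimes exactly) collinear across environments, so
  attribution cannot distinguish, say, a planted `tmean` window from the
  same days' GDD window even in principle. Planted-truth experiments
  therefore use factors outside these families (`rhmean`, `wsmean`,
  `radn`).
* **Environment-level sample size.** Window features vary only between
  environments, so the effective n for any window-phenotype association
  is the number of environments, regardless of how many plants were
  phenotyped. With 14 environments and ~1,900 windows, chance
  correlations routinely reach what a window explaining half the
  environmental variance achieves, and greedy trees then credit the
  lucky proxy. Attribution-recovery experiments therefore use a larger
  single-archetype panel (84 environments, 4 lines, 1 rep — holding the
  sample count modest), where between-environment variation is pure
  seeded weather noise and windows decorrelate across days. The
  regional archetype contrasts of the default mix are realistic but
  confound whole factor families (every precipitation window separates
  arid from humid sites), which is exactly why the scan's
  window-specific claims are strongest for within-region panels.

With that design, over 20 seeded datasets, both planted factors are
recovered with day-range Jaccard ≥ 0.5 in ≥ 90% of seeds while the
selected windows stay under 3% of the 1,898 env features — the
sparsity regime the selection threshold is meant to produce. The scan's
recovery experiment plants a single radiation window and calibrates
genotype and residual noise so the planted signal is ~60% of
observation-level variance, then checks the argmax-|r| window over 20
seeds.

## Numerical choices and degenerate inputs

* Daily GDD is clamped at 0 (no negative degree-days); PTQ and PRDTR
  are defined as 0 when their denominators are ≤ 0. Both rules are in
  `derive_daily_indices()` and documented there.
* Windows are closed intervals on the 1-based day-after-planting axis;
  the column key `"<factor>_<start>_<end>"` encodes them.
* PCA uses column-centered, unscaled markers; each component's sign is
  fixed so its largest-magnitude loading is positive, making scores
  reproducible across platforms.
* Constant vectors make a correlation undefined: the scan marks such
  windows `NA`, and `pearson_with_p()` raises an error rather than
  returning a silent 0.
* An all-constant phenotype yields an all-zero ANOVA table with a
  warning and variance shares defined as 0.
* Genotypes observed in fewer than 3 environments are excluded from the
  FW regression with a warning; GGE requires a complete mean table and
  says so rather than imputing.

## Problem sizes used by the tests

The shipped tests and the acceptance script run the full 150-day,
13-factor, 1,898-window grid but scale the panel: 4–40 lines and 1–3
reps depending on the check, 14 environments for pipeline and CV
checks, 84 single-archetype environments for attribution recovery, 20
seeds for recovery rates, and 10 seeds for the feature-selection
comparison. These sizes are the package's choice of experiment: large
enough for the recovery rates to be stable, small enough that the whole
suite reruns routinely.

## Known limitations

* Variance shares are SS percentages from a fixed-effects fit, not
  variance components; with severe unbalance they depend on the stated
  stratum order.
* The scan's p-values are unadjusted and its windows heavily overlap;
  neighbouring windows carry nearly identical information.
* TreeSHAP here is the path-dependent variant; with strongly dependent
  features its attributions (like the original) spread credit along
  correlated windows.
* Selection sharpness degrades as the number of environments falls;
  with a 14-environment panel the selected set should be read as
  factor-plus-period families, not day-exact claims.
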