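---
title: "Methods: longitudinal parallel mediation with multiple imputation and bootstrap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal parallel mediation with multiple imputation and bootstrap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(panelmediate)
```

# The model and its assumptions

`panelmediate` analyses a two-wave panel design with a focal predictor $X$
measured at wave 1, three parallel mediators $M_1, M_2, M_3$ and an outcome
$Y$ measured at wave 2, and lagged wave-1 measures $U_1,\dots,U_4$ of the
four repeated constructs entering every equation as covariates. The system
is five OLS regressions:

$$\hat M_{ji} = i_{Mj} + a_j X_i + \textstyle\sum_k u_{jk} U_{ki} \qquad (j = 1,2,3)$$
$$\hat Y_i = i_Y + c' X_i + b_1 M_{1i} + b_2 M_{2i} + b_3 M_{3i} + \textstyle\sum_k u_k U_{ki}$$
$$\hat Y_i = c_0 + c_1 X_i + \textstyle\sum_k c_{k+1} U_{ki}$$

The estimands are the specific indirect effects $a_j b_j$ (outcome-scale
points per point of the predictor), their sum (the total indirect effect),
the direct effect $c'$, and the total effect $c_1$. Because all equations
share the same covariate set, the algebraic decomposition
$c_1 = c' + \sum_j a_j b_j$ holds *exactly* on any completed dataset; the
package preserves it at the pooled level by pooling indirect effects as
means of per-imputation products (see below). Inference is associational:
"parallel" means no causal paths among the mediators are modelled, and no
claim is made about unmeasured confounding.

Classical (homoskedastic) OLS standard errors are used, matching the
$t$/fractional-df reporting style the design is typically paired with.
Variables are never standardized: effects are interpreted per raw scale
point.

# Missing data

## Imputation model

Missingness of 28–38% per variable is addressed by multiple imputation
under a joint multivariate-normal model over the nine analysis variables,
the four wave-0 auxiliary measures, age, binary gender, and dummy-coded
immigrant generation. The sampler is classical data augmentation:

* **I-step** — each row's missing block is drawn from its conditional
  normal given the row's observed entries and the current $(\mu, \Sigma)$.
  The implementation conditions through the precision matrix
  $\Omega = \Sigma^{-1}$: the conditional covariance is
  $\Omega_{mm}^{-1}$ and the conditional mean
  $\mu_m - \Omega_{mm}^{-1}\Omega_{mo}(y_o - \mu_o)$, so each missingness
  pattern only factorizes its (small) missing block.
* **P-step** — $(\mu, \Sigma)$ is drawn from the normal–inverse-Wishart
  posterior under a diffuse Jeffreys-style prior given the completed data
  ($\Sigma \sim \mathrm{IW}(n-1, S)$, $\mu \mid \Sigma \sim N(\bar y, \Sigma/n)$).

A ridge of $10^{-6}$ (configurable) is added whenever a covariance draw is
numerically non-positive-definite. The proprietary "model-based" imputation
engine used in the motivating study is closed; joint-normal data
augmentation over the same variable set is a standard, asymptotically
congenial approximation for an OLS analysis model, and equivalence is not
claimed. A fully-conditional-specification engine (per-variable Bayesian
normal regressions) and a complete-case baseline are provided for the
sensitivity grid, not as the primary engine.

Imputed scale scores are **clipped to their response bounds but not
rounded** to the Likert grid — scale scores are item means and
quasi-continuous. Imputed gender is rounded to $\{0,1\}$ and generation to
the nearest category via its dummies; these only ever serve as covariates.

## Convergence gating and imputation draws

`n_chains` (default 2) chains run from overdispersed starts (extra chains
offset by ±2 observed SDs) for `burn_in` iterations (default 5000). The
Gelman–Rubin potential scale reduction factor is computed on the second
half of the monitored trajectory of every mean and variance parameter as
$\widehat R = \sqrt{((L-1)/L\,W + B/L)/W}$; all values must fall below
`psrf_threshold` (default 1.05) or imputation aborts (an explicit `force`
override is logged). The M (default 100) completed datasets are then saved
from the first chain every $\lfloor\text{post\_burn\_iterations}/M\rfloor$
iterations (defaults 10000/100 = spacing 100). Spacing matters: saving
imputations at short spacing autocorrelates them, understates
between-imputation variance, and measurably inflates the type-I error of
the pooled bootstrap interval — the package's null-calibration test keeps
the 100-iteration spacing even in its reduced-scale runs for exactly this
reason.

## Pooling

Per-imputation fits are pooled by Rubin's rules: $\bar Q$, within-variance
$\bar W$, between-variance $B$, total $T = \bar W + (1 + 1/M)B$, with
Barnard–Rubin adjusted degrees of freedom using complete-data df
$n - p - 1$ (fractional, never exceeding the complete-data df). Indirect
effects are pooled as **means of per-imputation products**, which keeps the
decomposition identity exact under pooling; the product of pooled paths is
reported alongside for comparison.

# Bootstrap inference on indirect effects

Products of regression coefficients are not normal in finite samples, so
intervals come from the percentile bootstrap, in either nesting order:

* **Imputation-then-bootstrap** (primary): from each of the M completed
  datasets draw B case resamples (rows with replacement, size $n$), refit
  the path system, and record each indirect effect; all $M \times B$ draws
  are pooled per effect (100,000 at the default M = 100, B = 1000).
* **Bootstrap-then-imputation** (sensitivity alternative): draw B case
  resamples of the *incomplete* table, impute each `m_per_boot` times
  (default 2) with a short-burn-in chain (default 500 — full 5000-iteration
  chains per replicate would be computationally disproportionate), and use
  the mean of the per-imputation products as that replicate's draw.

Interval bounds follow the inverse-empirical-CDF convention: the
$\lceil np \rceil$-th order statistic at $p = \alpha/2$ and $1-\alpha/2$.
At these draw counts competing quantile conventions differ only in the
fourth decimal, but the convention is fixed and tested. A replicate whose
resampled design is rank-deficient (or, under BTI, loses every observed
value of some variable) is redrawn, counted, and capped. The significance
flag is simply whether the interval excludes zero.

# The synthetic-data generator

The generator is the package's ground truth and encodes the study
conditions of the motivating cohort:

* **Wave-1/0 block** ($X$, $U_1..U_4$, four auxiliaries): a Gaussian copula
  with *moment-matched scaled-Beta margins* — each margin reproduces the
  published complete-case mean and SD exactly in expectation while
  respecting its response bounds (e.g. the predictor's 4.10/2.71 on 1–9).
  The latent copula correlations are calibrated by Gauss–Hermite quadrature
  so the *realized Pearson* correlations match the published bivariate
  table (an uncalibrated copula with these skewed margins attenuates them
  by roughly 10%). The auxiliaries attach through a persistence
  construction with the same-construct cross-wave correlations
  (0.47/0.37/0.28/0.56), which keeps the joint correlation matrix positive
  definite by construction.
* **Wave-2 equations**: each mediator is generated from its structural
  equation with the published path magnitudes as defaults
  ($a = (0.019, 0.032, 0.005)$, $b = (0.001, 0.117, 0.011)$,
  $c' = -0.004$, published lagged-covariate coefficients and intercepts),
  then truncated to its bounds. Residual SDs are solved at configuration
  time so pre-truncation marginal SDs match the published wave-2 SDs. The
  three mediator equations receive *correlated* residuals, calibrated so
  the generated mediator intercorrelations match the published values
  (0.43/0.44/0.30) — shared lagged predictors alone induce only ≈ 0.19.
  The outcome residual stays independent so the $b$-paths remain the
  equations' estimands.
* **Missingness**: MCAR, or (default) MAR with per-variable logistic
  masking driven by the standardized auxiliary composite (loading −1.0:
  lower prior regard/self-esteem predicts dropout), gender (+0.35) and age
  (+0.25), with each variable's intercept solved by root-finding so the
  expected rate equals its target (34% for the predictor, 38% for wave-2,
  28–29% for wave-1). Auxiliaries and demographics are never masked, which
  makes the default mechanism genuinely MAR given always-observed
  predictors — deliberately, so that imputation is testable against truth.
  The motivating study does not characterize its mechanism; this is an
  assumption consistent with its use of wave-0 auxiliaries.
* **Demographics** are independent: gender Bernoulli(0.49), generation
  (25/55/20%), age $\sim N(12.5, 0.95)$ clipped to 10–16 — a plausible
  middle-school profile, irrelevant to the estimands.
* **Items**: `generate_items()` produces parallel Likert items whose common
  correlation solves the Spearman–Brown relation at the instrument's target
  alpha, rounds to the grid, clips to bounds, and stores negatively worded
  items on the administered metric. Round-trip recovery of alpha is within
  about 0.03 (rounding attenuates slightly).

**Seed policy**: one master seed; every stage (generation, masking, each
chain, each bootstrap stream) derives its own child seed deterministically
from the master seed and a stage label, so a single replicate can be
replayed in isolation and identical seeds reproduce every output file
byte-for-byte.

## What the generator does and does not emulate

It emulates the published univariate moments, correlation structure,
reliabilities, path magnitudes, and missingness rates. It does **not**
emulate non-normal latent shapes beyond the Beta margins, MNAR mechanisms,
item-level missingness, clustering within schools, or measurement
non-invariance across waves. Passing tests therefore demonstrate that the
machinery recovers truth under a realistic but well-specified MAR world;
they cannot certify behaviour under MNAR dropout or severe model
misspecification.

## Truncation attenuation and the recovery oracle

Two of the published wave-2 means sit close to their scale ceilings
(private regard 4.18 with SD 0.78 near 5; public regard 3.38 with SD 0.85
on a 1–4 scale). Bound-censoring of generated scores therefore attenuates
the *observable* $a_2$ and $a_3$ slopes by roughly 14–15% relative to the
latent structural coefficients (b-paths by only 1–3%); the package's
regression test measures and guards this envelope (< 20% on a-paths). For
this reason parameter-recovery tests compare estimates to the generator's
**induced estimand** — the large-n complete-data OLS limit — rather than to
the latent coefficient. That is also the correct target for validating the
imputation machinery: multiple imputation should recover what complete data
would estimate, not undo censoring.

A related note on the schema: the private-regard instrument is administered
on four response options, yet the published complete-case means for it
exceed 4 at both waves; the default schema therefore bounds private regard
at 1–5 (the only bounds under which those moments are attainable).

# Numerical and design choices

* Scale scores are prorated item means: reverse items recoded
  $v \mapsto \min + \max - v$, a score requires at least half the items
  observed (`min_prop_observed = 0.5`, configurable) — standard
  psychometric practice where the instrument documentation specifies only
  "the average of the items". Cronbach's alpha is computed on
  listwise-complete rows, matching conventional reporting.
* The missingness mask is the `NA` pattern of the tibble;
  `missingness_mask()` derives the explicit boolean matrix, so mask/data
  agreement holds by construction and bounds are enforced at construction
  and on CSV read.
* Degenerate cases: zero total-score variance, fewer than 2 items or 3
  complete rows (alpha); rank-deficient designs (estimation error;
  bootstrap redraw); zero within-chain variance with separated chains
  (PSRF error); constant variables in descriptives (NA correlation with a
  logged note); a variable with no observed values (imputation error).
* Ties and caps: bootstrap redraws are capped (default `max(100, B)`);
  generation categories resolve by first-maximum on their dummies.
* The sensitivity grid does not try to reproduce the motivating study's
  exact 25-variant enumeration (which is not published in full); it is a
  configurable cross of engines × orders × covariate sets with per-variant
  seeds, a concordance summary, and failure isolation. The complete-case
  engine draws all its interval draws from the bootstrap (its M is 1) and
  is not held to MI's power in tests, since listwise deletion discards
  most rows at these missingness rates.
* This package is used from R; the pipeline surface is
  `run_mediation_pipeline()` / `run_sensitivity_grid()` plus the exported
  stage functions, with a run manifest (seeds, configs, PSRF, redraw
  counts) sufficient to replay any variant.

## Problem sizes used by the test suite

The suite exercises the full procedure at reduced scale, chosen so the
statistical property under test — not runtime — determines the design:
chain lengths of a few hundred iterations (the joint-normal sampler for
~17 variables mixes in tens of iterations; the 5000/10000 defaults are
conservative settings for real analyses), M of 3–20, B of 50–200,
parameter recovery over 50 replicate seeds at n = 900 with M = 20, and
null calibration over 200 replicates at n = 900 with M = 10, B = 100 and
100-iteration spacing. The draw-count check runs the published M = 100 ×
B = 1000 on a small panel. Tolerances follow the quantity's Monte-Carlo
error (e.g. 3 MC SEs for recovery, ±2 binomial SEs around 5% for
calibration) rather than fixed cosmetic thresholds.

# Known limitations

* The joint-normal imputation model treats bounded, skewed scale scores as
  normal; imputations are clipped to bounds, which is pragmatic rather than
  principled near ceilings.
* Percentile intervals (not BCa or studentized) and case resampling (not
  residual resampling) are the only bootstrap flavours, by design scope.
* Small-M imputation-then-bootstrap is mildly anti-conservative (the pooled
  draws carry between-imputation spread without the $(1+1/M)$ inflation);
  at M = 10 with proper spacing the null rejection rate is within the
  binomial band of 5% in the package's own calibration test, and the
  default M = 100 is safer still.
* No multilevel structure, no moderated mediation, no latent-variable
  (SEM) estimation, no MNAR sensitivity parameters.
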