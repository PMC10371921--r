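# panelmediate

Parallel multiple mediation for two-wave panel studies with substantial
missing data.

Longitudinal developmental studies often measure a predictor and a set of
candidate mediators and outcomes at successive waves, lose 30% or more of
each measure to attrition and nonresponse, and still need defensible
inference on *indirect* effects. `panelmediate` implements the complete
workflow for one widely used design — a focal predictor measured at wave 1,
three parallel mediators and an outcome at wave 2, lagged wave-1 measures of
every repeated construct as covariates, and an earlier auxiliary wave that
informs imputation. The motivating application is the study of how strongly
Latinx early adolescents felt affected by Arizona's SB 1070 immigration law
(a 1–9 scale), with ethnic centrality, ethnic private regard, and ethnic
public regard as parallel mediators of its association with later
self-esteem.

## The model

Five OLS equations with subject index *i*, predictor *X*, mediators
*M₁…M₃*, outcome *Y*, and lagged covariates *U₁…U₄*:

```
M_ji = i_Mj + a_j X_i + u_j1 U_1i + … + u_j4 U_4i + e_ji      (j = 1,2,3)
Y_i  = i_Y  + c' X_i + b_1 M_1i + b_2 M_2i + b_3 M_3i + Σ u_k U_ki + e_i
Y_i  = c_0  + c_1 X_i + c_2 U_1i + … + c_5 U_4i + e_i          (total effect)
```

The specific indirect effect through mediator *j* is the product `a_j b_j`,
the total indirect effect is `Σ a_j b_j`, and on any completed dataset the
decomposition `c_1 = c' + Σ a_j b_j` holds exactly.

Missing data are handled by multiple imputation via joint multivariate-normal
data augmentation (I-step/P-step Gibbs sampling over the analysis variables,
auxiliaries, and demographics), gated on the Gelman–Rubin potential scale
reduction factor (threshold 1.05). Coefficients are pooled by Rubin's rules
with Barnard–Rubin degrees of freedom. Inference on indirect effects uses the
percentile bootstrap in either nesting order: *imputation-then-bootstrap*
(B case resamples of each of M completed datasets, all M×B draws pooled) or
*bootstrap-then-imputation* (B resamples of the incomplete table, each
imputed with short chains). A synthetic-panel generator reproduces the
motivating study's published moments, correlations, path magnitudes, scale
reliabilities, and 28–38% missing-at-random missingness, so every stage is
testable against known ground truth.

## Worked example

The indirect effects implied by the published path coefficients of the
motivating study (bundled as `reference_path_estimates()`):

```r
library(panelmediate)
indirect_effects(reference_path_estimates())
#> # A tibble: 6 × 2
#>   effect          estimate
#>   <chr>              <dbl>
#> 1 indirect_m1     0.000019
#> 2 indirect_m2     0.00374
#> 3 indirect_m3     0.000055
#> 4 total_indirect  0.00382
#> 5 direct         -0.004
#> 6 total           0
```

Rounded to three decimals these are the published indirect-effect estimates:
0.000, 0.004, 0.000, and 0.004 — only the path through ethnic private
regard, and the total indirect effect, are distinguishable from zero.

A full reduced-scale analysis of a synthetic panel generated at the study
conditions (n = 900, 28–38% MAR missingness; M = 20 imputations spaced 100
iterations apart, B = 200 bootstrap resamples each):

```r
cfg <- simulation_config(n = 900, seed = 2024)
panel <- generate_panel(cfg) |> impose_missingness(cfg)
summarize_missingness(panel)
#> # A tibble: 16 × 4
#>   variable     n n_missing pct_missing
#>   <chr>    <int>     <int>       <dbl>
#> 1 x_t1       900       326        36.2
#> 2 m1_t2      900       335        37.2
#> 3 m2_t2      900       341        37.9
#> 4 m3_t2      900       323        35.9
#> 5 y_t2       900       347        38.6
#> # ℹ 11 more rows

fit <- bootstrap_mediation(
  panel,
  imputation_config(burn_in = 500, post_burn_iterations = 2000,
                    n_imputations = 20, n_chains = 2, seed = 2024),
  B = 200, seed = 2024)
tidy(fit)
#> # A tibble: 5 × 6
#>   effect           estimate     lower   upper level significant
#>   <chr>               <dbl>     <dbl>   <dbl> <dbl> <lgl>
#> 1 indirect_m1    -0.000123  -0.00177  0.00133  0.95 FALSE
#> 2 indirect_m2     0.00304    0.000268 0.00672  0.95 TRUE
#> 3 indirect_m3     0.0000515 -0.00125  0.00142  0.95 FALSE
#> 4 total_indirect  0.00297   -0.000107 0.00669  0.95 FALSE
#> 5 direct         -0.00789   -0.0222   0.00622  0.95 FALSE
```

The generator's structural private-regard product is 0.032 × 0.117 ≈ 0.0037
(bound-censoring near the scale ceiling attenuates the estimable effect
slightly; see the methods vignette); the pooled percentile interval flags
exactly that specific indirect effect, matching the qualitative pattern of
the published analysis (where the total indirect effect sat exactly on the
0.000 boundary).
`run_mediation_pipeline()` wraps the same stages behind one configuration
object with logging, table export, and a replayable manifest, and
`run_sensitivity_grid()` crosses imputation engines (joint data
augmentation, FCS, complete-case), bootstrap orders, and covariate sets.

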