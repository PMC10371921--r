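test_that("Rubin pooling reproduces hand-computed variance components", {
  # two fits with estimates 1 and 3, SEs 1:
  # Qbar = 2, W = 1, B = 2, T = 1 + (1 + 1/2) * 2 = 4
  pool <- pool_rubin(list(fake_fit(1), fake_fit(3)))
  est <- pool$estimates
  expect_equal(est$estimate, 2)
  expect_equal(est$w_within, 1)
  expect_equal(est$b_between, 2)
  expect_equal(est$std.error, sqrt(4))
  expect_lt(est$df, 100) # fractional, below the complete-data df
  expect_gt(est$df, 0)
})

test_that("pooling M identical fits degenerates to the single fit", {
  f <- fit_path_model(complete_panel(60, seed = 13))
  pool <- pool_rubin(list(f, f, f))
  expect_equal(pool$estimates$b_between, rep(0, nrow(pool$estimates)))
  expect_equal(pool$estimates$estimate, f$coefficients$estimate)
  expect_equal(pool$estimates$std.error, f$coefficients$std.error)
  expect_true(all(pool$estimates$df <= f$coefficients$df))
})

test_that("pooled estimates are means of per-imputation estimates", {
  pm <- incomplete_panel(120)
  mi <- impute_panel(pm, quick_imp_config(M = 4))
  fits <- lapply(mi$tables, fit_path_model)
  pool <- pool_rubin(fits)
  manual <- rowMeans(vapply(fits, function(f) f$coefficients$estimate,
                            numeric(nrow(fits[[1]]$coefficients))))
  expect_equal(pool$estimates$estimate, manual, tolerance = 1e-12)
  # between-imputation variance strictly positive under missingness
  x_rows <- pool$estimates$term == "x_t1"
  expect_true(all(pool$estimates$b_between[x_rows] > 0))
  expect_error(pool_rubin(list(fits[[1]], fake_fit(1))), "Inconsistent")
})

test_that("percentile intervals follow the sorted-order convention", {
  # inverse-empirical-CDF convention: bounds are the ceil(n*p) order stats
  ci <- percentile_ci(as.numeric(1:1000), level = 0.95)
  expect_equal(ci$lower, 25)
  expect_equal(ci$upper, 975)

  const <- percentile_ci(rep(0.4, 200))
  expect_equal(const$lower, 0.4)
  expect_equal(const$upper, 0.4)
  expect_true(const$significant)

  sym <- percentile_ci(c(-(1:100), 1:100) / 100)
  expect_false(sym$significant)

  expect_error(percentile_ci(rnorm(50)), "100 draws")
})

test_that("imputation-then-bootstrap pools exactly M x B draws per effect", {
  pm <- incomplete_panel(90)
  boot <- bootstrap_mediation(pm, quick_imp_config(M = 3), B = 60, seed = 14)
  expect_equal(boot$n_draws, 180)
  expect_equal(nrow(boot$draws), 180)
  expect_setequal(colnames(boot$draws),
                  c("indirect_m1", "indirect_m2", "indirect_m3",
                    "total_indirect", "direct"))
  expect_equal(nrow(boot$ci), 5)
  # point estimate equals mean over imputations of per-imputation products
  fits <- lapply(boot$mi_set$tables, fit_path_model)
  manual <- rowMeans(vapply(fits, function(f) indirect_effects(f)$estimate,
                            numeric(6)))
  expect_equal(boot$ci$estimate[boot$ci$effect == "indirect_m2"], manual[2],
               tolerance = 1e-12)
  # pooled-level decomposition under mean-of-products pooling
  pts <- boot$points
  expect_lt(abs(pts$estimate[pts$effect == "total"] -
                  pts$estimate[pts$effect == "direct"] -
                  pts$estimate[pts$effect == "total_indirect"]), 1e-8)
})

zero_outcome_noise_config <- function(n) {
  tm <- default_t1_moments()
  tm$mean <- c(5, 3, 3, 2.5, 2.5, 3, 3, 2.5, 2.5)
  tm$sd <- c(1.2, 0.4, 0.4, 0.35, 0.3, 0.4, 0.4, 0.35, 0.3)
  simulation_config(
    n = n, t1_moments = tm,
    intercepts = c(m1 = 1.5, m2 = 1.5, m3 = 1.2, y = 1.0),
    u_coefs = matrix(0.1, 4, 3), y_u_coefs = rep(0.05, 4),
    true_a = c(0.05, 0.08, 0.02), true_b = c(0.05, 0.1, 0.05),
    true_cprime = 0.02, resid_sds = c(0.2, 0.2, 0.2, 0),
    missing_rates = c(y_t2 = 0)
  )
}

test_that("noiseless directions give degenerate intervals", {
  # the outcome equation has zero residual noise, so every bootstrap
  # replicate recovers b and c' exactly; the interval for the direct
  # effect collapses to a point
  p <- generate_panel(zero_outcome_noise_config(120), seed = 15)
  boot <- bootstrap_mediation(p, quick_imp_config(M = 2, burn_in = 30),
                              B = 80, seed = 16)
  expect_equal(unname(boot$draws[, "direct"]), rep(0.02, 160),
               tolerance = 1e-8)
  ci_d <- boot$ci[boot$ci$effect == "direct", ]
  expect_equal(ci_d$lower, ci_d$upper, tolerance = 1e-10)
  expect_equal(ci_d$lower, 0.02, tolerance = 1e-8)
  expect_true(ci_d$significant)
  # the a-paths carry sampling noise, so the products still vary
  expect_gt(sd(boot$draws[, "indirect_m2"]), 0)
})

test_that("bootstrap-then-imputation reduces to the case bootstrap when complete", {
  p <- generate_panel(zero_outcome_noise_config(100), seed = 17)
  boot <- bootstrap_mediation(p, quick_imp_config(M = 2, burn_in = 20),
                              B = 120, order = "bootstrap_then_imputation",
                              m_per_boot = 2, bti_burn_in = 20, seed = 18)
  expect_equal(boot$n_draws, 120)
  # complete data make the inner imputation the identity, so each draw is
  # an ordinary case-bootstrap refit: the noiseless direct effect is exact
  expect_equal(unname(boot$draws[, "direct"]), rep(0.02, 120),
               tolerance = 1e-8)
  expect_gt(sd(boot$draws[, "indirect_m2"]), 0)
})

test_that("both nesting orders agree on a strong synthetic effect", {
  cfg <- default_config(400, true_a = c(0.019, 0.15, 0.005),
                        true_b = c(0.001, 0.30, 0.011))
  pm <- impose_missingness(generate_panel(cfg, seed = 19), cfg, seed = 20)
  itb <- bootstrap_mediation(pm, quick_imp_config(M = 4, seed = 21), B = 50,
                             seed = 21)
  bti <- bootstrap_mediation(pm, quick_imp_config(M = 4, seed = 21), B = 200,
                             order = "bootstrap_then_imputation",
                             m_per_boot = 2, bti_burn_in = 60, seed = 22,
                             mi_set = itb$mi_set)
  ci_itb <- itb$ci[itb$ci$effect == "indirect_m2", ]
  ci_bti <- bti$ci[bti$ci$effect == "indirect_m2", ]
  expect_true(ci_itb$significant)
  expect_true(ci_bti$significant)
  # intervals overlap substantially
  expect_lt(max(ci_itb$lower, ci_bti$lower), min(ci_itb$upper, ci_bti$upper))
})

test_that("interval width shrinks stochastically with sample size", {
  widths <- vapply(c(200, 800, 3200), function(n) {
    cfg <- default_config(n, missing_rates = c(y_t2 = 0))
    p <- generate_panel(cfg, seed = 23)
    boot <- bootstrap_mediation(p, quick_imp_config(M = 2, burn_in = 20),
                                B = 80, seed = 24)
    ci <- boot$ci[boot$ci$effect == "indirect_m2", ]
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
})
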