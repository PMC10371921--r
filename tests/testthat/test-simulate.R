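test_that("the generator is seed-deterministic", {
  cfg <- default_config(120)
  a <- generate_panel(cfg, seed = 11)
  b <- generate_panel(cfg, seed = 11)
  c <- generate_panel(cfg, seed = 12)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(simulation_config(n = 5), "n >= 10")
  bad_corr <- default_t1_corr()
  bad_corr[1, 2] <- 0.9 # asymmetric
  expect_error(simulation_config(t1_corr = bad_corr), "symmetric")
  npd <- matrix(0.999, 9, 9)
  diag(npd) <- 1
  npd[1, 2] <- npd[2, 1] <- -0.999
  expect_error(simulation_config(t1_corr = npd), "positive definite")
  expect_error(simulation_config(missing_rates = c(x_t1 = 1)), "\\[0, 1\\)")
  # infeasible marginal variance for the bounds
  tm <- default_t1_moments()
  tm$sd[1] <- 5
  expect_error(simulation_config(t1_moments = tm), "infeasible")
})

test_that("generated T1 margins match the configured study moments", {
  p <- complete_panel(10000, seed = 21)
  expect_equal(mean(p$x_t1), 4.10, tolerance = 0.03)
  expect_equal(sd(p$x_t1), 2.71, tolerance = 0.03)
  expect_equal(mean(p$u2_t1), 4.29, tolerance = 0.02)
  expect_equal(sd(p$u4_t1), 0.51, tolerance = 0.02)
  # every score respects its bounds (constructor validates, but check a few)
  expect_true(all(p$x_t1 >= 1 & p$x_t1 <= 9))
  expect_true(all(p$m3_t2 >= 1 & p$m3_t2 <= 4))
})

test_that("a null configuration yields null fitted effects at large n", {
  cfg <- default_config(8000, true_a = c(0, 0, 0), true_cprime = 0)
  f <- fit_path_model(generate_panel(cfg, seed = 31))
  cf <- f$coefficients
  for (eq in c("m1", "m2", "m3", "y")) {
    est <- cf[cf$equation == eq & cf$term == "x_t1", ]
    expect_lt(abs(est$estimate), 4 * est$std.error)
  }
  eff <- indirect_effects(f)
  expect_lt(max(abs(eff$estimate[1:4])), 0.005)
})

test_that("complete-data OLS recovers the induced paths over replicates", {
  cfg <- default_config(2500,
    true_a = c(0.02, 0.03, 0.01), true_b = c(0.00, 0.12, 0.01)
  )
  oracle <- pseudo_true_paths(cfg)
  reps <- 8
  a2 <- b2 <- numeric(reps)
  for (r in seq_len(reps)) {
    f <- fit_path_model(generate_panel(cfg, seed = 500 + r))
    cf <- f$coefficients
    a2[r] <- cf$estimate[cf$equation == "m2" & cf$term == "x_t1"]
    b2[r] <- cf$estimate[cf$equation == "y" & cf$term == "m2_t2"]
  }
  expect_lt(abs(mean(a2) - oracle$a[2]), 3 * sd(a2) / sqrt(reps))
  expect_lt(abs(mean(b2) - oracle$b[2]), 3 * sd(b2) / sqrt(reps))
})

test_that("with zero noise and no truncation the structural equations hold exactly", {
  # mid-scale configuration whose linear predictors stay inside all bounds
  tm <- default_t1_moments()
  tm$mean <- c(5, 3, 3, 2.5, 2.5, 3, 3, 2.5, 2.5)
  tm$sd <- c(1.2, 0.4, 0.4, 0.35, 0.3, 0.4, 0.4, 0.35, 0.3)
  cfg <- simulation_config(
    n = 400, t1_moments = tm,
    intercepts = c(m1 = 1.5, m2 = 1.5, m3 = 1.2, y = 1.0),
    u_coefs = matrix(0.1, 4, 3), y_u_coefs = rep(0.05, 4),
    true_a = c(0.05, 0.08, 0.02), true_b = c(0.05, 0.1, 0.05),
    true_cprime = 0.02, resid_sds = c(0, 0, 0, 0)
  )
  p <- generate_panel(cfg, seed = 77)
  u <- as.matrix(as.data.frame(p)[c("u1_t1", "u2_t1", "u3_t1", "u4_t1")])
  m2_expected <- 1.5 + 0.08 * p$x_t1 + drop(u %*% rep(0.1, 4))
  expect_true(all(m2_expected > 1 & m2_expected < 5)) # no truncation active
  expect_equal(p$m2_t2, m2_expected, tolerance = 1e-12)
  y_expected <- 1.0 + 0.02 * p$x_t1 + 0.05 * p$m1_t2 + 0.1 * p$m2_t2 +
    0.05 * p$m3_t2 + drop(u %*% rep(0.05, 4))
  expect_equal(p$y_t2, y_expected, tolerance = 1e-12)

  # noiseless identification: with mediator noise present (so the outcome
  # design is full rank) but a noiseless outcome equation, the fitted
  # outcome coefficients equal the generating ones exactly
  cfg2 <- simulation_config(
    n = 400, t1_moments = tm,
    intercepts = c(m1 = 1.5, m2 = 1.5, m3 = 1.2, y = 1.0),
    u_coefs = matrix(0.1, 4, 3), y_u_coefs = rep(0.05, 4),
    true_a = c(0.05, 0.08, 0.02), true_b = c(0.05, 0.1, 0.05),
    true_cprime = 0.02, resid_sds = c(0.2, 0.2, 0.2, 0)
  )
  f <- fit_path_model(generate_panel(cfg2, seed = 78))
  cf <- f$coefficients
  expect_equal(cf$estimate[cf$equation == "y" & cf$term == "m2_t2"], 0.1,
               tolerance = 1e-8)
  expect_equal(cf$estimate[cf$equation == "y" & cf$term == "x_t1"], 0.02,
               tolerance = 1e-8)
})

test_that("bound-censoring attenuation stays within the measured envelope", {
  # regression guard: under the default study conditions (private/public
  # regard means near their scale ceilings) censoring attenuates the
  # a-paths by roughly 14-15% and b2 by ~1%; alert if this drifts
  cfg <- default_config(40000)
  f <- fit_path_model(generate_panel(cfg, seed = 61))
  cf <- f$coefficients
  a2 <- cf$estimate[cf$equation == "m2" & cf$term == "x_t1"]
  b2 <- cf$estimate[cf$equation == "y" & cf$term == "m2_t2"]
  expect_lt(abs(1 - a2 / cfg$true_a[2]), 0.20)
  expect_lt(abs(1 - b2 / cfg$true_b[2]), 0.12)
})

test_that("MCAR masking hits its rates and leaves auxiliaries intact", {
  cfg <- default_config(5000, missing_mechanism = "mcar")
  p <- generate_panel(cfg, seed = 41)
  pm <- impose_missingness(p, cfg, seed = 42)
  expect_equal(mean(is.na(pm$y_t2)), 0.38, tolerance = 0.025)
  expect_equal(mean(is.na(pm$x_t1)), 0.34, tolerance = 0.025)
  expect_false(anyNA(pm$aux1_t0))
  expect_false(anyNA(pm$gender))
  # observed values unchanged
  keep <- !is.na(pm$y_t2)
  expect_identical(pm$y_t2[keep], p$y_t2[keep])
})

test_that("zero rates leave the panel untouched", {
  cfg <- default_config(100, missing_rates = c(y_t2 = 0))
  p <- generate_panel(cfg, seed = 51)
  expect_identical(tibble::as_tibble(impose_missingness(p, cfg)),
                   tibble::as_tibble(p))
})

test_that("MAR calibration matches targets and is detectable; MCAR is not", {
  n <- 5000
  cfg_mar <- default_config(n, missing_mechanism = "mar")
  p <- generate_panel(cfg_mar, seed = 71)
  pm <- impose_missingness(p, cfg_mar, seed = 72)
  # intercept search calibrates expected rates to the targets (+-2 points)
  for (v in names(cfg_mar$missing_rates)) {
    expect_equal(mean(is.na(pm[[v]])), cfg_mar$missing_rates[[v]],
                 tolerance = 0.02)
  }
  # masked and unmasked groups differ in the T0 auxiliary composite
  auxm <- rowMeans(as.data.frame(p)[paste0("aux", 1:4, "_t0")])
  d_mar <- t.test(auxm[is.na(pm$y_t2)], auxm[!is.na(pm$y_t2)])
  expect_lt(d_mar$p.value, 1e-6)

  cfg_mcar <- default_config(n, missing_mechanism = "mcar")
  pm2 <- impose_missingness(p, cfg_mcar, seed = 73)
  d_mcar <- t.test(auxm[is.na(pm2$y_t2)], auxm[!is.na(pm2$y_t2)])
  expect_gt(d_mcar$p.value, 0.01)
})

test_that("item generation round-trips the target reliability", {
  p <- complete_panel(10000, seed = 81)
  sb <- default_scales()$sb1070
  items <- generate_items(p$x_t1, sb, seed = 82)
  expect_equal(cronbach_alpha(items), 0.92, tolerance = 0.03)
  # item means track the supplied scores
  expect_gt(cor(rowMeans(items), p$x_t1), 0.9)

  pub <- default_scales()$public_regard
  items3 <- generate_items(p$m3_t2, pub, seed = 83)
  expect_equal(cronbach_alpha(items3), 0.81, tolerance = 0.03)

  # near-perfect reliability makes items nearly identical
  hi <- scale_definition("hi", 4, 1, 9, target_alpha = 0.995)
  items_hi <- generate_items(p$x_t1, hi, seed = 84)
  expect_gt(cor(items_hi[, 1], items_hi[, 2]), 0.95)

  # reverse-worded items are stored on the administered metric
  se <- default_scales()$self_esteem
  items_se <- generate_items(p$y_t2, se, seed = 85)
  expect_lt(cor(items_se[, 1], items_se[, se$reverse_items[1]]), 0)

  expect_error(generate_items(p$x_t1, scale_definition("x", 4, 1, 9,
                                                       target_alpha = NA)),
               "positive")
  bad <- scale_definition("x", 4, 1, 9, target_alpha = 1)
  expect_error(generate_items(p$x_t1, bad), "infeasible")
})

test_that("the simulation config serializes to a JSON sidecar", {
  path <- withr::local_tempfile(fileext = ".json")
  cfg <- default_config(120)
  write_simulation_config(cfg, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n, 120)
  expect_equal(unlist(back$true_a), c(0.019, 0.032, 0.005))
  expect_length(back$t1_corr, 9)
  expect_equal(back$missing_mechanism, "mar")
})

test_that("item-level generation attaches a full item battery", {
  cfg <- default_config(200, item_level = TRUE)
  p <- generate_panel(cfg, seed = 91)
  items <- attr(p, "items")
  expect_named(items, c("x_t1", "m1_t2", "m2_t2", "m3_t2", "y_t2",
                        "u1_t1", "u2_t1", "u3_t1", "u4_t1"))
  expect_equal(dim(items$x_t1), c(200, 4))
  expect_equal(dim(items$y_t2), c(200, 10))
  expect_true(all(items$x_t1 >= 1 & items$x_t1 <= 9))
})
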