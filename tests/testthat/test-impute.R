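test_that("a fully observed table passes through imputation unchanged", {
  p <- complete_panel(80)
  mi <- impute_panel(p, quick_imp_config(M = 4, burn_in = 50))
  expect_length(mi$tables, 4)
  for (tt in mi$tables) {
    expect_identical(tibble::as_tibble(tt), tibble::as_tibble(p))
  }
})

test_that("observed cells are never altered and imputations vary", {
  pm <- incomplete_panel(150)
  mi <- impute_panel(pm, quick_imp_config(M = 5, burn_in = 200))
  expect_length(mi$tables, 5)
  mask <- missingness_mask(pm)
  vars <- setdiff(names(pm), "subject_id")
  for (tt in mi$tables) {
    expect_false(anyNA(as.data.frame(tt)[analysis_vars()]))
    for (v in vars) {
      obs <- !mask[, v]
      expect_identical(tt[[v]][obs], pm[[v]][obs])
    }
  }
  # for variables with missing cells, imputed values differ across tables
  miss_y <- mask[, "y_t2"]
  imp1 <- mi$tables[[1]]$y_t2[miss_y]
  imp2 <- mi$tables[[2]]$y_t2[miss_y]
  expect_false(isTRUE(all.equal(imp1, imp2)))
  # imputed continuous values are clipped to scale bounds, not rounded
  expect_true(all(mi$tables[[1]]$y_t2 >= 1 & mi$tables[[1]]$y_t2 <= 4))
  expect_gt(mean(mi$tables[[1]]$y_t2[miss_y] %% 1 != 0), 0.5)
})

test_that("imputed demographics land on valid categories", {
  p <- tibble::as_tibble(complete_panel(120))
  p$gender[1:30] <- NA
  p$generation[1:30] <- NA
  pm <- panel_table(p)
  mi <- impute_panel(pm, quick_imp_config(M = 3, burn_in = 150))
  for (tt in mi$tables) {
    expect_true(all(tt$gender %in% c(0, 1)))
    expect_true(all(tt$generation %in% 1:3))
  }
})

test_that("across-imputation means track the conditional-normal oracle", {
  # u1 linear in x with known slope; 30% MCAR on u1. The across-imputation
  # mean of each imputed cell should approach the regression prediction
  # given the observed x (the conditional mean under the joint normal).
  set.seed(900)
  n <- 400
  x <- pmin(pmax(rnorm(n, 5, 1.2), 1), 9)
  u1 <- pmin(pmax(3 + 0.45 * (x - 5) + rnorm(n, 0, 0.3), 1), 5)
  df <- tibble::tibble(subject_id = as.character(1:n), x_t1 = x, u1_t1 = u1)
  miss <- seq_len(n) %in% sample.int(n, 120)
  df$u1_t1[miss] <- NA
  pm <- panel_table(df)
  cfg <- quick_imp_config(M = 40, burn_in = 100, post = 400, seed = 11)
  cfg$variables <- c("x_t1", "u1_t1")
  mi <- impute_panel(pm, cfg)
  imputed <- vapply(mi$tables, function(tt) tt$u1_t1[miss], numeric(sum(miss)))
  avg_imp <- rowMeans(imputed)
  fit <- lm(u1_t1 ~ x_t1, data = df[!miss, ])
  oracle <- predict(fit, newdata = df[miss, ])
  expect_lt(abs(mean(avg_imp - oracle)), 0.08)
  expect_gt(cor(avg_imp, oracle), 0.8)
})

test_that("long-run chain means agree with the MAR maximum likelihood oracle", {
  # bivariate monotone MAR: x always observed, u1 missing more often for
  # low x. The ML estimate of mu_u1 has the closed form
  # alpha + beta * mean(x) from the complete-case regression.
  set.seed(901)
  n <- 500
  x <- pmin(pmax(rnorm(n, 5, 1.2), 1), 9)
  u1 <- pmin(pmax(3 + 0.5 * (x - 5) + rnorm(n, 0, 0.3), 1), 5)
  p_miss <- plogis(1.2 - 0.45 * x)
  miss <- runif(n) < p_miss
  df <- tibble::tibble(subject_id = as.character(1:n), x_t1 = x, u1_t1 = u1)
  df$u1_t1[miss] <- NA
  cc <- lm(u1_t1 ~ x_t1, data = df[!miss, ])
  mle_mu <- unname(coef(cc)[1] + coef(cc)[2] * mean(x))

  cfg <- imputation_config(burn_in = 2000, post_burn_iterations = 10,
                           n_imputations = 10, n_chains = 2,
                           variables = c("x_t1", "u1_t1"), seed = 13)
  chains <- run_data_augmentation(panel_table(df), cfg)
  mu_chain <- chains$chains[[1]]$monitor[, 2] # mu of u1_t1
  half <- mu_chain[seq.int(length(mu_chain) / 2, length(mu_chain))]
  expect_equal(mean(half), mle_mu, tolerance = 0.05)
})

test_that("PSRF follows its defining formula across regimes", {
  # identical chains: between-chain variance 0, PSRF = 1 up to (L-1)/L
  set.seed(3)
  m <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("p1", "p2")))
  d <- compute_psrf(list(m, m), threshold = 1.05)
  expect_equal(d$psrf$psrf, c(1, 1), tolerance = 0.01)
  expect_true(d$converged)

  # non-overlapping chains: PSRF far above the gate
  c1 <- matrix(rnorm(100, 0, 0.01), 100, 1)
  c2 <- matrix(rnorm(100, 10, 0.01), 100, 1)
  d2 <- compute_psrf(list(c1, c2), threshold = 1.05)
  expect_gt(d2$psrf$psrf[1], 50)
  expect_false(d2$converged)

  # iid draws from the same distribution: PSRF within [1, 1.05]
  set.seed(4)
  a <- matrix(rnorm(20000), 20000, 1)
  b <- matrix(rnorm(20000), 20000, 1)
  d3 <- compute_psrf(list(a, b), threshold = 1.05)
  expect_gt(d3$psrf$psrf[1], 0.999)
  expect_lt(d3$psrf$psrf[1], 1.05)

  expect_error(compute_psrf(list(m), threshold = 1.05), "2 chains")
  short <- matrix(rnorm(10), 10, 1)
  expect_error(compute_psrf(list(short, short)), "10 retained")
  flat <- matrix(1, 100, 1)
  up <- matrix(2, 100, 1)
  expect_error(compute_psrf(list(flat, up)), "within-chain variance")
})

test_that("the convergence gate blocks deliberately non-mixed chains", {
  pm <- incomplete_panel(60)
  bad <- imputation_config(burn_in = 24, post_burn_iterations = 10,
                           n_imputations = 2, n_chains = 2,
                           overdispersion = 80, seed = 5)
  expect_error(impute_panel(pm, bad), "not converged")
  mi <- suppressWarnings(impute_panel(pm, bad, force = TRUE))
  expect_length(mi$tables, 2)
})

test_that("imputation counts and spacing follow the configuration", {
  expect_error(imputation_config(post_burn_iterations = 5, n_imputations = 10),
               "at least")
  pm <- incomplete_panel(70)
  mi <- impute_panel(pm, quick_imp_config(M = 7, post = 70))
  expect_length(mi$tables, 7)
})

test_that("variables with zero observed values are rejected", {
  df <- tibble::as_tibble(complete_panel(30))
  df$y_t2 <- NA_real_
  expect_error(impute_panel(panel_table(df), quick_imp_config(M = 2)),
               "zero observed")
})

test_that("the FCS engine preserves observed data and completes the panel", {
  pm <- incomplete_panel(120)
  mi <- impute_panel(pm, quick_imp_config(M = 3), engine = "fcs")
  expect_length(mi$tables, 3)
  expect_identical(mi$engine, "fcs")
  mask <- missingness_mask(pm)
  for (tt in mi$tables) {
    expect_false(anyNA(as.data.frame(tt)[analysis_vars()]))
    obs <- !mask[, "y_t2"]
    expect_identical(tt$y_t2[obs], pm$y_t2[obs])
  }
})
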