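#' Default first-wave moments for the synthetic panel
#'
#' Complete-case means, SDs and response bounds of the T1 predictor and the
#' four T1 repeated measures, as reported for the motivating cohort; the T0
#' auxiliary measures reuse the moments of their T1 counterparts (the study
#' reports no T0 descriptives).
#'
#' @return Tibble with columns `variable`, `mean`, `sd`, `lo`, `hi`.
#' @export
default_t1_moments <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd,  ~lo, ~hi,
    "x_t1",    4.10,  2.71, 1,   9,
    "u1_t1",   3.65,  0.79, 1,   5,
    "u2_t1",   4.29,  0.70, 1,   5,
    "u3_t1",   3.44,  0.83, 1,   4,
    "u4_t1",   2.96,  0.51, 1,   4,
    "aux1_t0", 3.65,  0.79, 1,   5,
    "aux2_t0", 4.29,  0.70, 1,   5,
    "aux3_t0", 3.44,  0.83, 1,   4,
    "aux4_t0", 2.96,  0.51, 1,   4
  )
}

#' Default correlation matrix of the T1/T0 block
#'
#' The five T1 variables carry the reported complete-case bivariate
#' correlations. The T0 auxiliaries are attached through a persistence
#' construction `aux_j = c_j * u_j + sqrt(1 - c_j^2) * e_j`, with
#' persistence coefficients equal to the same-construct cross-wave
#' correlations observed between T1 and T2 (0.47, 0.37, 0.28, 0.56); this
#' keeps the 9 x 9 matrix positive definite by construction.
#'
#' @return A 9 x 9 correlation matrix over
#'   `(x_t1, u1_t1..u4_t1, aux1_t0..aux4_t0)`.
#' @export
default_t1_corr <- function() {
  r5 <- matrix(c(
    1.00, 0.18, 0.23, 0.03, -0.12,
    0.18, 1.00, 0.50, 0.43, 0.26,
    0.23, 0.50, 1.00, 0.32, 0.25,
    0.03, 0.43, 0.32, 1.00, 0.28,
    -0.12, 0.26, 0.25, 0.28, 1.00
  ), 5, 5, byrow = TRUE)
  persist <- c(0.47, 0.37, 0.28, 0.56)
  r <- matrix(0, 9, 9)
  r[1:5, 1:5] <- r5
  for (j in 1:4) {
    # corr(aux_j, v) = c_j * corr(u_j, v); corr(aux_j, aux_k) = c_j c_k r_jk
    r[5 + j, 1:5] <- persist[j] * r5[1 + j, ]
    r[1:5, 5 + j] <- r[5 + j, 1:5]
    for (k in 1:4) {
      r[5 + j, 5 + k] <- if (j == k) 1 else persist[j] * persist[k] * r5[1 + j, 1 + k]
    }
  }
  vars <- default_t1_moments()$variable
  dimnames(r) <- list(vars, vars)
  r
}

default_missing_rates <- function() {
  c(
    x_t1 = 0.34, m1_t2 = 0.38, m2_t2 = 0.38, m3_t2 = 0.38, y_t2 = 0.38,
    u1_t1 = 0.28, u2_t1 = 0.28, u3_t1 = 0.28, u4_t1 = 0.29
  )
}

#' Default correlation targets among the three T2 mediators
#'
#' Used to calibrate the residual correlations of the mediator equations so
#' the generated mediators reproduce the published T2 intercorrelations
#' (which shared T1 predictors alone cannot).
#'
#' @return Symmetric 3 x 3 correlation matrix over `(m1, m2, m3)`.
#' @export
default_t2_mediator_corr <- function() {
  r <- matrix(c(1, 0.43, 0.44, 0.43, 1, 0.30, 0.44, 0.30, 1), 3, 3)
  dimnames(r) <- list(c("m1", "m2", "m3"), c("m1", "m2", "m3"))
  r
}

# Probabilists' Gauss-Hermite nodes/weights by Golub-Welsch: integrates
# f against the standard normal density.
gauss_hermite_prob <- function(k) {
  j <- sqrt(seq_len(k - 1))
  jac <- matrix(0, k, k)
  jac[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- j
  jac[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- j
  e <- eigen(jac, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# Latent copula correlations such that the transformed (scaled-Beta) margins
# attain the target Pearson correlations: per pair, solve
# corr(g_i(z1), g_j(z2)) = r_target over the latent bivariate-normal
# correlation by root-finding with Gauss-Hermite quadrature.
calibrate_copula_corr <- function(target_corr, t1_moments, k = 24) {
  gh <- gauss_hermite_prob(k)
  p <- nrow(target_corr)
  g <- vector("list", p)
  mom1 <- mom2 <- numeric(p)
  for (i in seq_len(p)) {
    sh <- beta_shapes(t1_moments$mean[i], t1_moments$sd[i],
                      t1_moments$lo[i], t1_moments$hi[i])
    g[[i]] <- local({
      sh_i <- sh
      lo_i <- t1_moments$lo[i]
      hi_i <- t1_moments$hi[i]
      function(z) lo_i + (hi_i - lo_i) * qbeta(pnorm(z), sh_i[1], sh_i[2])
    })
    vals <- g[[i]](gh$nodes)
    mom1[i] <- sum(gh$weights * vals)
    mom2[i] <- sum(gh$weights * vals^2)
  }
  sds <- sqrt(mom2 - mom1^2)
  implied_r <- function(rho, i, j) {
    # E[g_i(z1) g_j(rho z1 + sqrt(1-rho^2) u)]
    s <- sqrt(max(1 - rho^2, 0))
    acc <- 0
    for (a in seq_len(k)) {
      z2 <- rho * gh$nodes[a] + s * gh$nodes
      acc <- acc + gh$weights[a] * g[[i]](gh$nodes[a]) *
        sum(gh$weights * g[[j]](z2))
    }
    (acc - mom1[i] * mom1[j]) / (sds[i] * sds[j])
  }
  out <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      r_t <- target_corr[i, j]
      if (abs(r_t) < 1e-12) next
      rho <- uniroot(function(r) implied_r(r, i, j) - r_t,
                     c(-0.999, 0.999), tol = 1e-6)$root
      out[i, j] <- out[j, i] <- rho
    }
  }
  # restore positive definiteness if the pairwise solutions broke it
  e <- eigen(out, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    v <- pmax(e$values, 1e-8)
    out <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
  }
  dimnames(out) <- dimnames(target_corr)
  out
}

# Shape parameters of a Beta distribution rescaled to [lo, hi] matching a
# target mean/SD; errors when the variance is infeasible for the bounds.
beta_shapes <- function(mean, sd, lo, hi) {
  m <- (mean - lo) / (hi - lo)
  v <- (sd / (hi - lo))^2
  if (m <= 0 || m >= 1) abort("Target mean must lie strictly inside the bounds.")
  if (v >= m * (1 - m)) {
    abort(sprintf("SD %.3g infeasible for mean %.3g on [%g, %g].", sd, mean, lo, hi))
  }
  nu <- m * (1 - m) / v - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

#' Configuration of the synthetic two-wave panel generator
#'
#' The defaults reproduce the study conditions of the motivating cohort:
#' first-wave moments and correlations from the published descriptive
#' tables, structural paths at the published magnitudes, and per-variable
#' missingness targets of 28--38% under a missing-at-random mechanism driven
#' by the always-observed T0 auxiliaries and demographics.
#'
#' Residual SDs of the four T2 equations are solved at configuration time so
#' the implied marginal T2 SDs match the published values (0.85, 0.78, 0.85,
#' 0.53) before truncation to the scale bounds.
#'
#' @param n Sample size (>= 10).
#' @param true_a Length-3 vector of predictor-to-mediator paths.
#' @param true_b Length-3 vector of mediator-to-outcome paths.
#' @param true_cprime Direct effect of the predictor on the outcome.
#' @param u_coefs 4 x 3 matrix: coefficients of the lagged covariates
#'   `u1..u4` (rows) in each mediator equation (columns).
#' @param y_u_coefs Length-4 vector: lagged-covariate coefficients in the
#'   outcome equation.
#' @param intercepts Length-4 named-order vector `(m1, m2, m3, y)`.
#' @param t1_moments Tibble as [default_t1_moments()].
#' @param t1_corr 9 x 9 positive-definite correlation matrix.
#' @param t2_sds Target marginal SDs of `(m1, m2, m3, y)` used to solve the
#'   residual SDs; ignored when `resid_sds` is supplied.
#' @param t2_corr Target 3 x 3 correlation matrix of the mediators, used to
#'   calibrate the residual correlations of the mediator equations.
#' @param resid_sds Optional length-4 vector of residual SDs `(m1, m2, m3, y)`.
#' @param missing_mechanism `"mar"` or `"mcar"`.
#' @param missing_rates Named per-variable masking rates in `[0, 1)`.
#' @param item_level If `TRUE`, [generate_panel()] also simulates item-level
#'   responses for each scored scale (attached as attribute `items`).
#' @param seed Integer master seed; `NULL` uses the current RNG stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 900,
                              true_a = c(0.019, 0.032, 0.005),
                              true_b = c(0.001, 0.117, 0.011),
                              true_cprime = -0.004,
                              u_coefs = cbind(
                                m1 = c(0.463, 0.104, 0.022, -0.048),
                                m2 = c(0.109, 0.355, 0.034, 0.173),
                                m3 = c(0.070, -0.015, 0.310, 0.266)
                              ),
                              y_u_coefs = c(-0.022, -0.029, 0.013, 0.568),
                              intercepts = c(m1 = 1.286, m2 = 1.461,
                                             m3 = 1.303, y = 0.952),
                              t1_moments = default_t1_moments(),
                              t1_corr = default_t1_corr(),
                              t2_sds = c(m1 = 0.85, m2 = 0.78, m3 = 0.85, y = 0.53),
                              t2_corr = default_t2_mediator_corr(),
                              resid_sds = NULL,
                              missing_mechanism = c("mar", "mcar"),
                              missing_rates = default_missing_rates(),
                              item_level = FALSE,
                              seed = NULL) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(
    is_scalar_number(n), n >= 10,
    length(true_a) == 3, length(true_b) == 3, is_scalar_number(true_cprime),
    is.matrix(u_coefs), all(dim(u_coefs) == c(4, 3)),
    length(y_u_coefs) == 4, length(intercepts) == 4,
    is.matrix(t1_corr), all(dim(t1_corr) == c(9, 9))
  )
  if (max(abs(t1_corr - t(t1_corr))) > 1e-10 || any(abs(diag(t1_corr) - 1) > 1e-10)) {
    abort("`t1_corr` must be symmetric with unit diagonal.")
  }
  ev <- eigen(t1_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) abort("`t1_corr` must be positive definite.")
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    abort("`missing_rates` must lie in [0, 1).")
  }
  # check marginal feasibility now, not at generation time
  for (i in seq_len(nrow(t1_moments))) {
    beta_shapes(t1_moments$mean[i], t1_moments$sd[i],
                t1_moments$lo[i], t1_moments$hi[i])
  }
  cfg <- structure(
    list(
      n = as.integer(n), true_a = true_a, true_b = true_b,
      true_cprime = true_cprime, u_coefs = u_coefs, y_u_coefs = y_u_coefs,
      intercepts = intercepts, t1_moments = t1_moments, t1_corr = t1_corr,
      t2_sds = t2_sds, t2_corr = t2_corr, resid_sds = resid_sds,
      missing_mechanism = missing_mechanism, missing_rates = missing_rates,
      item_level = isTRUE(item_level), seed = seed
    ),
    class = "simulation_config"
  )
  rr <- solve_resid_structure(cfg)
  if (is.null(cfg$resid_sds)) cfg$resid_sds <- rr$sds
  cfg$resid_corr <- rr$corr
  cfg$copula_corr <- calibrate_copula_corr(t1_corr, t1_moments)
  cfg
}

# Residual SDs making the pre-truncation marginal T2 variances hit t2_sds,
# and residual correlations of the mediator equations making the implied
# mediator intercorrelations hit t2_corr (shared T1 predictors alone induce
# far weaker mediator correlations than observed). Uses the target
# covariance of the T1 block. Variances floored at 0.04.
solve_resid_structure <- function(cfg) {
  sds5 <- cfg$t1_moments$sd[1:5]
  sig5 <- diag(sds5) %*% cfg$t1_corr[1:5, 1:5] %*% diag(sds5)
  w <- rbind(cfg$true_a, cfg$u_coefs) # 5 x 3, rows (x, u1..u4)
  resid_m <- numeric(3)
  for (j in 1:3) {
    lp_var <- drop(t(w[, j]) %*% sig5 %*% w[, j])
    resid_m[j] <- sqrt(max(cfg$t2_sds[j]^2 - lp_var, 0.04))
  }
  shared <- t(w) %*% sig5 %*% w # mediator covariance from shared predictors
  resid_corr <- diag(3)
  for (j in 1:2) {
    for (k in seq.int(j + 1, 3)) {
      target_cov <- cfg$t2_corr[j, k] * cfg$t2_sds[j] * cfg$t2_sds[k]
      rho <- (target_cov - shared[j, k]) / (resid_m[j] * resid_m[k])
      resid_corr[j, k] <- resid_corr[k, j] <- clip(rho, -0.9, 0.9)
    }
  }
  e <- eigen(resid_corr, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    v <- pmax(e$values, 1e-8)
    resid_corr <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(resid_corr))
    resid_corr <- resid_corr / tcrossprod(d)
  }
  # covariance of (x, u1..u4, m1..m3) implied by the linear system
  sig8 <- matrix(0, 8, 8)
  sig8[1:5, 1:5] <- sig5
  cross <- sig5 %*% w # cov(t1 vars, m_j)
  sig8[1:5, 6:8] <- cross
  sig8[6:8, 1:5] <- t(cross)
  sig8[6:8, 6:8] <- shared +
    diag(resid_m) %*% resid_corr %*% diag(resid_m)
  v <- c(cfg$true_cprime, cfg$y_u_coefs, cfg$true_b)
  lp_var_y <- drop(t(v) %*% sig8 %*% v)
  resid_y <- sqrt(max(cfg$t2_sds[4]^2 - lp_var_y, 0.04))
  list(
    sds = stats::setNames(c(resid_m, resid_y), c("m1", "m2", "m3", "y")),
    corr = resid_corr
  )
}

#' Generate a fully observed synthetic two-wave panel
#'
#' The T1/T0 block is drawn from a Gaussian copula with the configured
#' correlation matrix and moment-matched scaled-Beta margins (so sample
#' means and SDs track the configured values exactly in expectation and all
#' scores respect their bounds). Each T2 mediator is then generated from its
#' structural equation \eqn{M_j = i_j + a_j X + u' U + e_j}, the outcome from
#' \eqn{Y = i_Y + c' X + b' M + u' U + e_Y}, and T2 values are truncated to
#' their scale bounds. Demographics are drawn independently. The seed fully
#' determines the output.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A fully observed [panel_table()]; the generating parameters are
#'   attached as attribute `true_params`, and item-level responses as
#'   attribute `items` when `config$item_level` is set.
#' @export
generate_panel <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    n <- config$n
    tm <- config$t1_moments
    latent_corr <- config$copula_corr %||% config$t1_corr
    z <- matrix(rnorm(n * 9), n, 9) %*% chol(latent_corr)
    t1 <- matrix(NA_real_, n, 9, dimnames = list(NULL, tm$variable))
    for (i in 1:9) {
      sh <- beta_shapes(tm$mean[i], tm$sd[i], tm$lo[i], tm$hi[i])
      t1[, i] <- tm$lo[i] +
        (tm$hi[i] - tm$lo[i]) * qbeta(pnorm(z[, i]), sh[1], sh[2])
    }
    x <- t1[, "x_t1"]
    u <- t1[, c("u1_t1", "u2_t1", "u3_t1", "u4_t1")]
    schema <- default_panel_schema()
    bounds <- function(v) unlist(schema[schema$variable == v, c("lo", "hi")])
    m <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("m1_t2", "m2_t2", "m3_t2")))
    resid_corr <- config$resid_corr %||% diag(3)
    e_m <- matrix(rnorm(n * 3), n, 3) %*% chol(resid_corr)
    for (j in 1:3) {
      eta <- config$intercepts[j] + config$true_a[j] * x +
        drop(u %*% config$u_coefs[, j])
      b <- bounds(colnames(m)[j])
      m[, j] <- clip(eta + config$resid_sds[j] * e_m[, j], b[1], b[2])
    }
    eta_y <- config$intercepts[4] + config$true_cprime * x +
      drop(m %*% config$true_b) + drop(u %*% config$y_u_coefs)
    by <- bounds("y_t2")
    y <- clip(eta_y + rnorm(n, 0, config$resid_sds[4]), by[1], by[2])

    gender <- rbinom(n, 1, 0.49)
    generation <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.55, 0.20))
    age <- round(clip(rnorm(n, 12.5, 0.95), 10, 16), 1)

    tbl <- tibble::tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      x_t1 = x, m1_t2 = m[, 1], m2_t2 = m[, 2], m3_t2 = m[, 3], y_t2 = y,
      u1_t1 = u[, 1], u2_t1 = u[, 2], u3_t1 = u[, 3], u4_t1 = u[, 4],
      aux1_t0 = t1[, "aux1_t0"], aux2_t0 = t1[, "aux2_t0"],
      aux3_t0 = t1[, "aux3_t0"], aux4_t0 = t1[, "aux4_t0"],
      gender = as.numeric(gender), generation = as.numeric(generation),
      age = age
    )
    out <- panel_table(tbl, schema = schema)
    attr(out, "true_params") <- list(
      a = config$true_a, b = config$true_b, cprime = config$true_cprime,
      u_coefs = config$u_coefs, y_u_coefs = config$y_u_coefs,
      intercepts = config$intercepts, resid_sds = config$resid_sds,
      resid_corr = config$resid_corr
    )
    if (config$item_level) {
      attr(out, "items") <- simulate_panel_items(out)
    }
    out
  })
}

# Item-level responses for each scored scale of a generated panel.
simulate_panel_items <- function(tbl, scales = default_scales()) {
  map <- c(
    x_t1 = "sb1070", m1_t2 = "centrality", m2_t2 = "private_regard",
    m3_t2 = "public_regard", y_t2 = "self_esteem",
    u1_t1 = "centrality", u2_t1 = "private_regard", u3_t1 = "public_regard",
    u4_t1 = "self_esteem"
  )
  out <- list()
  for (v in names(map)) {
    sc <- scales[[map[[v]]]]
    # private regard is administered on 4 response options but scored on the
    # 1-5 metric in this cohort's descriptives; keep the declared bounds
    out[[v]] <- generate_items(tbl[[v]], sc)
  }
  out
}

#' Impose MCAR or MAR missingness on a complete panel
#'
#' Under MCAR each target cell is masked independently at its configured
#' rate. Under MAR the masking probability of each target variable is a
#' logistic function of the fully observed T0 auxiliary composite, gender,
#' and age, with the intercept calibrated by root-finding so the expected
#' masking rate equals the target exactly. T0 auxiliaries and demographics
#' are never masked.
#'
#' @param tbl A fully observed [panel_table()].
#' @param config A [simulation_config()]; uses its mechanism and rates.
#' @param seed Optional seed override.
#' @return A [panel_table()] with `NA` cells in the target variables.
#' @export
impose_missingness <- function(tbl, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  rates <- config$missing_rates
  targets <- names(rates)[rates > 0]
  missing_targets <- setdiff(targets, names(tbl))
  if (length(missing_targets)) {
    abort(sprintf("Missingness targets absent from the table: %s",
                  paste(missing_targets, collapse = ", ")))
  }
  if (!length(targets)) return(tbl)
  seed <- seed %||% (if (!is.null(config$seed)) child_seed(config$seed, "mask"))
  with_seed(seed, {
    n <- nrow(tbl)
    df <- tibble::as_tibble(tbl)
    if (config$missing_mechanism == "mcar") {
      for (v in targets) {
        df[[v]][runif(n) < rates[[v]]] <- NA_real_
      }
    } else {
      aux <- c("aux1_t0", "aux2_t0", "aux3_t0", "aux4_t0")
      preds <- intersect(c(aux, "gender", "age"), names(df))
      if (!length(preds) || anyNA(df[preds])) {
        abort("MAR requires fully observed T0 auxiliaries and demographics.")
      }
      aux_mean <- rowMeans(scale(as.matrix(df[intersect(aux, preds)])))
      s <- -1.0 * aux_mean
      if ("gender" %in% preds) s <- s + 0.35 * df$gender
      if ("age" %in% preds) s <- s + 0.25 * drop(scale(df$age))
      for (v in targets) {
        f <- function(b0) mean(plogis(b0 + s)) - rates[[v]]
        b0 <- uniroot(f, c(-30, 30), tol = 1e-10)$root
        df[[v]][runif(n) < plogis(b0 + s)] <- NA_real_
      }
    }
    out <- panel_table(df, schema = panel_schema(tbl))
    attr(out, "true_params") <- attr(tbl, "true_params")
    out
  })
}

#' Simulate parallel item responses consistent with a target reliability
#'
#' Items are generated as `score + noise` with noise variance chosen so the
#' common inter-item correlation \eqn{\rho} solves the Spearman-Brown
#' relation \eqn{\alpha = k\rho / (1 + (k-1)\rho)} at the scale's target
#' alpha; responses are then rounded to the Likert grid and clipped to the
#' scale bounds (which attenuates the recovered alpha slightly).
#'
#' @param scores Numeric vector of true scale scores.
#' @param scale A [scale_definition()] with a `target_alpha` in `(0, 1)`.
#' @param seed Optional seed.
#' @return Integer matrix `length(scores)` x `item_count`.
#' @export
generate_items <- function(scores, scale, seed = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  alpha <- scale$target_alpha
  if (is.na(alpha) || alpha <= 0) abort("`target_alpha` must be positive.")
  if (alpha >= 1) abort("`target_alpha` = 1 is infeasible with finite item noise.")
  k <- scale$item_count
  rho <- alpha / (k - alpha * (k - 1))
  with_seed(seed, {
    sigma_t2 <- var(scores, na.rm = TRUE)
    sigma_e <- sqrt(sigma_t2 * (1 - rho) / rho)
    n <- length(scores)
    items <- matrix(scores, n, k) + matrix(rnorm(n * k, 0, sigma_e), n, k)
    items <- round(items)
    items <- clip(items, scale$response_min, scale$response_max)
    if (length(scale$reverse_items)) {
      # stored responses are on the administered (unreversed) wording
      items[, scale$reverse_items] <-
        scale$response_min + scale$response_max - items[, scale$reverse_items]
    }
    storage.mode(items) <- "integer"
    colnames(items) <- sprintf("%s_item%d", scale$name, seq_len(k))
    items
  })
}

#' Write the simulation configuration (and true parameters) as JSON
#'
#' @param config A [simulation_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  x <- config
  x$t1_moments <- as.data.frame(x$t1_moments)
  x$t1_corr <- unclass(x$t1_corr)
  x$u_coefs <- unclass(x$u_coefs)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
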