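#' Pool path-model fits across imputations by Rubin's rules
#'
#' For each coefficient, the pooled estimate is the mean of the M
#' per-imputation estimates; the total variance combines the mean
#' within-imputation variance and the between-imputation variance,
#' \eqn{T = \bar W + (1 + 1/M) B}; degrees of freedom use the
#' Barnard-Rubin small-sample formula with complete-data residual df
#' \eqn{n - p - 1}, so they are fractional and never exceed the
#' complete-data df.
#'
#' @param fits List of [fit_path_model()] results over the M imputations
#'   (identical equation specifications).
#' @return An object of class `mi_pool` with an `estimates` tibble
#'   (`equation`, `term`, `estimate`, `std.error`, `statistic`, `df`,
#'   `p.value`, `b_between`, `w_within`, `lambda`, `fmi`).
#' @export
pool_rubin <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "path_fit")))
  keys <- lapply(fits, function(f) paste(f$coefficients$equation,
                                         f$coefficients$term))
  if (!all(vapply(keys, identical, TRUE, keys[[1]]))) {
    abort("Inconsistent equation specifications across imputations.")
  }
  m_imp <- length(fits)
  est <- vapply(fits, function(f) f$coefficients$estimate,
                numeric(nrow(fits[[1]]$coefficients)))
  ses <- vapply(fits, function(f) f$coefficients$std.error,
                numeric(nrow(fits[[1]]$coefficients)))
  est <- matrix(est, ncol = m_imp)
  ses <- matrix(ses, ncol = m_imp)
  qbar <- rowMeans(est)
  wbar <- rowMeans(ses^2)
  b <- if (m_imp > 1) apply(est, 1, var) else rep(0, nrow(est))
  t_var <- wbar + (1 + 1 / m_imp) * b
  lambda <- ifelse(t_var > 0, (1 + 1 / m_imp) * b / t_var, 0)
  nu_com <- fits[[1]]$coefficients$df
  nu_obs <- nu_com * (nu_com + 1) / (nu_com + 3) * (1 - lambda)
  df_br <- ifelse(
    lambda > 0 & m_imp > 1,
    {
      nu_old <- (m_imp - 1) / pmax(lambda, .Machine$double.eps)^2
      nu_old * nu_obs / (nu_old + nu_obs)
    },
    nu_obs
  )
  se <- sqrt(t_var)
  stat <- qbar / se
  riv <- ifelse(wbar > 0, (1 + 1 / m_imp) * b / wbar, 0)
  fmi <- (riv + 2 / (df_br + 3)) / (1 + riv)
  structure(
    list(
      estimates = tibble::tibble(
        equation = fits[[1]]$coefficients$equation,
        term = fits[[1]]$coefficients$term,
        estimate = qbar, std.error = se, statistic = stat,
        df = df_br, p.value = 2 * pt(-abs(stat), df_br),
        b_between = b, w_within = wbar, lambda = lambda, fmi = fmi
      ),
      m = m_imp, n = fits[[1]]$n
    ),
    class = "mi_pool"
  )
}

#' @export
print.mi_pool <- function(x, ...) {
  cat(sprintf("<mi_pool> %d coefficients pooled over M = %d imputations\n",
              nrow(x$estimates), x$m))
  print(x$estimates, n = 12)
  invisible(x)
}

#' Pooled indirect effects across imputations
#'
#' The pooled point estimate of each indirect effect is the mean over
#' imputations of the per-imputation products (which preserves the
#' decomposition identity at the pooled level); the product of the pooled
#' paths is reported alongside for comparison.
#'
#' @param fits List of [fit_path_model()] results.
#' @return Tibble with `effect`, `estimate` (mean of products), and
#'   `product_of_pooled`.
#' @export
pooled_indirect_effects <- function(fits) {
  per <- vapply(fits, function(f) indirect_effects(f)$estimate, numeric(6))
  per <- matrix(per, nrow = 6)
  pooled <- pool_rubin(fits)
  pop <- indirect_effects(pooled$estimates)
  tibble::tibble(
    effect = indirect_effects(fits[[1]])$effect,
    estimate = rowMeans(per),
    product_of_pooled = pop$estimate
  )
}

#' Percentile bootstrap confidence interval
#'
#' Bounds are the empirical \eqn{\alpha/2} and \eqn{1 - \alpha/2} quantiles
#' of the pooled draws under the inverse-empirical-CDF convention: the
#' \eqn{\lceil np \rceil}-th order statistic. The interval is significant
#' when it excludes zero.
#'
#' @param draws Numeric vector of bootstrap draws (at least 100).
#' @param level Confidence level (default 0.95).
#' @param point Optional point estimate carried into the result.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `level`,
#'   `significant`.
#' @export
percentile_ci <- function(draws, level = 0.95, point = NA_real_) {
  stopifnot(is.numeric(draws), is_scalar_number(level), level > 0, level < 1)
  if (length(draws) < 100) {
    abort("Percentile CI needs at least 100 draws.")
  }
  alpha <- 1 - level
  s <- sort(draws)
  n <- length(s)
  # inverse empirical CDF: Q(p) = ceil(n * p)-th order statistic
  q <- s[pmin(pmax(ceiling(n * c(alpha / 2, 1 - alpha / 2) - 1e-9), 1L), n)]
  tibble::tibble(
    estimate = point, lower = q[1], upper = q[2], level = level,
    significant = !(q[1] <= 0 && q[2] >= 0)
  )
}

mediation_effects <- c("indirect_m1", "indirect_m2", "indirect_m3",
                       "total_indirect", "direct")

#' Percentile-bootstrap inference on the indirect effects
#'
#' Two nesting orders are available. `imputation_then_bootstrap` (the
#' primary analysis) draws `B` case-resampled datasets from each of the M
#' completed datasets, refits the path system in every replicate, and pools
#' all M x B draws of each effect into one percentile interval.
#' `bootstrap_then_imputation` case-resamples the *incomplete* table `B`
#' times, multiply-imputes each resample with a short-burn-in chain, and
#' uses the mean of the `m_per_boot` per-imputation products as that
#' replicate's draw. Point estimates are the means over imputations of the
#' per-imputation products, from an imputation of the original table.
#'
#' @param tbl An incomplete (or complete) [panel_table()].
#' @param imp_config [imputation_config()] for the primary imputation.
#' @param B Bootstrap replicates per imputed dataset (ITB) or in total (BTI).
#' @param order `"imputation_then_bootstrap"` or
#'   `"bootstrap_then_imputation"`.
#' @param level Confidence level (default 0.95).
#' @param m_per_boot BTI only: imputations per bootstrap replicate
#'   (default 2).
#' @param bti_burn_in BTI only: burn-in of the short chains (default 500).
#' @param covariates Extra covariates for all equations.
#' @param seed Master seed for the bootstrap streams.
#' @param mi_set Optionally, a precomputed [impute_panel()] result for the
#'   original table (avoids re-imputing).
#' @param max_redraws Cap on redraws of degenerate replicates.
#' @return An object of class `boot_mediation`: effect draws, point
#'   estimates, percentile CIs, and bookkeeping.
#' @export
bootstrap_mediation <- function(tbl, imp_config = imputation_config(),
                                B = 1000,
                                order = c("imputation_then_bootstrap",
                                          "bootstrap_then_imputation"),
                                level = 0.95, m_per_boot = 2,
                                bti_burn_in = 500,
                                covariates = character(), seed = NULL,
                                mi_set = NULL, max_redraws = NULL) {
  order <- match.arg(order)
  seed <- seed %||% imp_config$seed
  max_redraws <- max_redraws %||% max(100L, as.integer(B))
  if (is.null(mi_set)) {
    cfg <- imp_config
    cfg$seed <- if (!is.null(seed)) child_seed(seed, "impute")
    mi_set <- impute_panel(tbl, cfg)
  }
  fits <- lapply(mi_set$tables, fit_path_model, covariates = covariates)
  points <- pooled_indirect_effects(fits)
  ex <- expand_covariates(as.data.frame(tbl), covariates)
  eqs <- boot_eq_spec(ex$cols)
  redraws <- 0L
  if (order == "imputation_then_bootstrap") {
    m_imp <- length(mi_set$tables)
    raw <- vector("list", m_imp)
    for (m in seq_len(m_imp)) {
      mat <- path_matrix(mi_set$tables[[m]], ex$cols)
      res <- with_seed(
        if (!is.null(seed)) child_seed(seed, paste0("boot", m)),
        boot_paths_cpp(mat, eqs, as.integer(B), as.integer(max_redraws))
      )
      redraws <- redraws + res$redraws
      raw[[m]] <- res$draws
    }
    raw <- do.call(rbind, raw)
  } else {
    raw <- matrix(NA_real_, B, 7)
    n <- nrow(tbl)
    short_cfg <- imputation_config(
      burn_in = bti_burn_in, post_burn_iterations = max(10L * m_per_boot, m_per_boot),
      n_imputations = m_per_boot, n_chains = 1
    )
    vars_needed <- unique(c(
      short_cfg$variables %||% intersect(default_imputation_vars(panel_schema(tbl)),
                                         names(tbl))
    ))
    for (b in seq_len(B)) {
      seed_b <- if (!is.null(seed)) child_seed(seed, paste0("bti", b))
      raw[b, ] <- with_seed(seed_b, {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          boot_tbl <- tibble::as_tibble(tbl)[idx, ]
          boot_tbl$subject_id <- sprintf("B%06d", seq_len(n))
          ok <- all(vapply(vars_needed, function(v) any(!is.na(boot_tbl[[v]])),
                           logical(1)))
          if (ok) {
            boot_ptbl <- panel_table(boot_tbl, schema = panel_schema(tbl))
            est <- tryCatch({
              mi_b <- impute_panel(boot_ptbl, short_cfg)
              per <- vapply(mi_b$tables, function(tt) {
                fit_paths_point(path_matrix(tt, ex$cols), eqs)
              }, numeric(7))
              rowMeans(matrix(per, nrow = 7))
            }, error = function(e) NULL)
            if (!is.null(est)) break
          }
          redraws <- redraws + 1L
          if (redraws > max_redraws) {
            abort("Too many degenerate bootstrap replicates (redraw cap hit).")
          }
        }
        est
      })
    }
  }
  colnames(raw) <- draw_col_names()
  draws <- effect_draws(raw)
  ci <- dplyr::bind_rows(lapply(mediation_effects, function(e) {
    pt <- points$estimate[match(e, points$effect)]
    dplyr::mutate(percentile_ci(draws[, e], level = level, point = pt),
                  effect = e, .before = 1)
  }))
  structure(
    list(
      draws = draws, ci = ci, points = points, order = order,
      B = as.integer(B), M = length(mi_set$tables),
      n_draws = nrow(draws), level = level, seed = seed,
      redraws = redraws, covariates = covariates, mi_set = mi_set
    ),
    class = "boot_mediation"
  )
}

#' @export
print.boot_mediation <- function(x, ...) {
  cat(sprintf(
    "<boot_mediation> %s: %d pooled draws per effect (M = %d, B = %d, %d redraws)\n",
    x$order, x$n_draws, x$M, x$B, x$redraws
  ))
  print(x$ci)
  invisible(x)
}

#' Write pooled coefficients as a regression-table CSV
#'
#' Columns `Model`, `Coeff`, `SE`, `t`, `df`, `p` (the layout of a pooled
#' regression results table).
#'
#' @param pool An `mi_pool` or `path_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_path_table <- function(pool, path) {
  est <- if (inherits(pool, "mi_pool")) pool$estimates else pool$coefficients
  out <- tibble::tibble(
    Model = est$equation, Term = est$term, Coeff = round(est$estimate, 3),
    SE = round(est$std.error, 3), t = round(est$statistic, 3),
    df = round(est$df, 3), p = round(est$p.value, 3)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write indirect-effect intervals as an effects-table CSV
#'
#' Columns `Effect`, `Estimate`, `LLCI`, `ULCI`, `Significant`.
#'
#' @param boot A `boot_mediation` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_indirect_table <- function(boot, path) {
  out <- tibble::tibble(
    Effect = boot$ci$effect, Estimate = round(boot$ci$estimate, 3),
    LLCI = round(boot$ci$lower, 3), ULCI = round(boot$ci$upper, 3),
    Significant = boot$ci$significant
  )
  readr::write_csv(out, path)
  invisible(path)
}
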