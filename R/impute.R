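#' Configuration of the multiple-imputation engine
#'
#' Joint multivariate-normal data augmentation over the analysis variables,
#' the T0 auxiliaries, age, gender, and dummy-coded immigrant generation.
#' Two (or more) chains are run from overdispersed starts for the burn-in
#' period; convergence is gated on the Gelman-Rubin potential scale
#' reduction factor before a further block of iterations is run on the
#' first chain, from which the M completed datasets are saved at equal
#' spacing.
#'
#' @param burn_in Burn-in iterations (default 5000).
#' @param post_burn_iterations Iterations after burn-in from which
#'   imputations are drawn (default 10000).
#' @param n_imputations Number of completed datasets M (default 100).
#' @param n_chains Number of chains for the PSRF diagnostic (>= 2).
#' @param psrf_threshold Convergence gate: all PSRFs must fall below this
#'   (default 1.05).
#' @param variables Variables in the imputation model; defaults to the nine
#'   analysis variables plus auxiliaries and demographics.
#' @param ridge Ridge added to near-singular covariance draws (default 1e-6).
#' @param overdispersion How many observed-data SDs the extra chains' start
#'   means are offset by (default 2).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(burn_in = 5000, post_burn_iterations = 10000,
                              n_imputations = 100, n_chains = 2,
                              psrf_threshold = 1.05, variables = NULL,
                              ridge = 1e-6, overdispersion = 2, seed = NULL) {
  stopifnot(
    is_scalar_number(burn_in), burn_in >= 0,
    is_scalar_number(post_burn_iterations), post_burn_iterations >= 1,
    is_scalar_number(n_imputations), n_imputations >= 1,
    is_scalar_number(n_chains), n_chains >= 1,
    is_scalar_number(psrf_threshold), psrf_threshold > 0
  )
  if (post_burn_iterations < n_imputations) {
    abort("`post_burn_iterations` must be at least `n_imputations`.")
  }
  structure(
    list(
      burn_in = as.integer(burn_in),
      post_burn_iterations = as.integer(post_burn_iterations),
      n_imputations = as.integer(n_imputations),
      n_chains = as.integer(n_chains),
      psrf_threshold = psrf_threshold, variables = variables,
      ridge = ridge, overdispersion = overdispersion, seed = seed
    ),
    class = "imputation_config"
  )
}

default_imputation_vars <- function(schema = default_panel_schema()) {
  c(analysis_vars(schema), auxiliary_vars(schema), demographic_vars(schema))
}

# Numeric matrix for the joint-normal model: generation enters as two
# dummies; everything else as-is. Returns the matrix plus the mapping needed
# to reconstruct panel columns.
build_impute_matrix <- function(tbl, variables) {
  absent <- setdiff(variables, names(tbl))
  if (length(absent)) {
    abort(sprintf("Imputation variables absent from the table: %s",
                  paste(absent, collapse = ", ")))
  }
  cols <- list()
  for (v in variables) {
    if (v == "generation") {
      g <- tbl[["generation"]]
      cols[["gen2"]] <- as.numeric(g == 2)
      cols[["gen3"]] <- as.numeric(g == 3)
    } else {
      cols[[v]] <- as.numeric(tbl[[v]])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  none_obs <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(none_obs)) {
    abort(sprintf("Variables with zero observed values: %s",
                  paste(none_obs, collapse = ", ")))
  }
  list(matrix = m, variables = variables)
}

# Group rows by missingness pattern; 0-based indices for the C++ core.
missingness_patterns <- function(m) {
  miss <- is.na(m)
  key <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(m)) - 1L, key)
  pats <- lapply(names(groups), function(k) {
    flags <- as.integer(strsplit(k, "")[[1]]) == 1L
    list(
      rows = as.integer(groups[[k]]),
      mis = as.integer(which(flags) - 1L),
      obs = as.integer(which(!flags) - 1L)
    )
  })
  pats
}

#' Run the data-augmentation burn-in chains
#'
#' Alternates the I-step (draw each row's missing entries from the
#' conditional normal given its observed entries and the current mean and
#' covariance) with the P-step (draw the mean and covariance from the
#' normal-inverse-Wishart posterior under a diffuse prior given the
#' completed data), in `n_chains` independent chains started from
#' overdispersed means. Chain trajectories of the mean vector and the
#' covariance diagonal are retained (thinned to at most 200 points) for the
#' PSRF diagnostic.
#'
#' @param tbl A [panel_table()] (possibly incomplete).
#' @param config An [imputation_config()].
#' @return An object of class `da_chains` holding per-chain monitors and
#'   final states.
#' @export
run_data_augmentation <- function(tbl, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  variables <- config$variables %||%
    intersect(default_imputation_vars(panel_schema(tbl)), names(tbl))
  info <- build_impute_matrix(tbl, variables)
  m <- info$matrix
  pats <- missingness_patterns(m)
  col_means <- colMeans(m, na.rm = TRUE)
  col_sds <- apply(m, 2, sd, na.rm = TRUE)
  col_sds[!is.finite(col_sds) | col_sds < 1e-8] <- 1e-4
  burn <- config$burn_in
  monitor_every <- max(1L, burn %/% 200L)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    offset <- if (k == 1) 0 else config$overdispersion * (-1)^k * ceiling((k - 1) / 2)
    mu0 <- col_means + offset * col_sds
    sigma0 <- diag(col_sds^2, ncol(m))
    y0 <- m
    for (j in seq_len(ncol(m))) y0[is.na(m[, j]), j] <- mu0[j]
    seed_k <- if (!is.null(config$seed)) child_seed(config$seed, paste0("chain", k))
    res <- with_seed(seed_k, {
      if (burn > 0) {
        da_gibbs_cpp(y0, lapply(pats, `[[`, "rows"), lapply(pats, `[[`, "mis"),
                     lapply(pats, `[[`, "obs"), burn, monitor_every,
                     integer(0), mu0, sigma0, config$ridge)
      } else {
        list(monitor = matrix(numeric(0), 0, 2 * ncol(m)),
             saves = list(), mu = mu0, sigma = sigma0)
      }
    })
    # completed data at the end of burn-in: redo a final I-step implicitly by
    # carrying the last completed matrix; the C++ core mutates `y` in place
    # on its own copy, so rebuild from the final state on the next call.
    chains[[k]] <- list(
      monitor = res$monitor, mu = res$mu, sigma = res$sigma,
      y = if (burn > 0) NULL else y0
    )
  }
  param_names <- c(colnames(m), paste0("var_", colnames(m)))
  structure(
    list(
      chains = chains, patterns = pats, matrix = m, variables = variables,
      param_names = param_names, table = tbl, config = config,
      monitor_every = monitor_every, y_init = NULL, col_means = col_means
    ),
    class = "da_chains"
  )
}

#' Gelman-Rubin potential scale reduction factors
#'
#' For each monitored scalar parameter,
#' \deqn{\widehat{R} = \sqrt{\frac{(L-1)/L \cdot W + B/L}{W}}}
#' with `W` the mean within-chain variance and `B` the between-chain
#' variance of the chain means times the chain length `L`. Only the second
#' half of the monitored trajectory is used. Convergence means every PSRF
#' falls below the threshold.
#'
#' @param chains A `da_chains` object from [run_data_augmentation()], or a
#'   list of equally sized iteration-by-parameter matrices (one per chain).
#' @param threshold Convergence threshold (default 1.05).
#' @return An object of class `mi_diagnostics`: a list with a `psrf` tibble,
#'   `converged`, `threshold`, `chain_length`, and `n_chains`.
#' @export
compute_psrf <- function(chains, threshold = 1.05) {
  if (inherits(chains, "da_chains")) {
    threshold <- chains$config$psrf_threshold
    mats <- lapply(chains$chains, `[[`, "monitor")
    params <- chains$param_names
  } else {
    mats <- chains
    params <- colnames(mats[[1]]) %||% paste0("param", seq_len(ncol(mats[[1]])))
  }
  if (length(mats) < 2) {
    abort("PSRF needs at least 2 chains.")
  }
  l_full <- nrow(mats[[1]])
  keep <- seq.int(max(1L, floor(l_full / 2) + 1L), l_full)
  if (length(keep) < 10) {
    abort("PSRF needs at least 10 retained iterations per chain.")
  }
  mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  l <- length(keep)
  p <- ncol(mats[[1]])
  psrf <- numeric(p)
  for (j in seq_len(p)) {
    draws <- vapply(mats, function(m) m[, j], numeric(l))
    w <- mean(apply(draws, 2, var))
    b <- l * var(colMeans(draws))
    if (w <= .Machine$double.eps) {
      if (b <= .Machine$double.eps) {
        psrf[j] <- 1
      } else {
        abort(sprintf("Zero within-chain variance for parameter %s.", params[j]))
      }
    } else {
      psrf[j] <- sqrt(((l - 1) / l * w + b / l) / w)
    }
  }
  structure(
    list(
      psrf = tibble::tibble(parameter = params, psrf = psrf),
      converged = all(psrf < threshold), threshold = threshold,
      chain_length = l, n_chains = length(mats)
    ),
    class = "mi_diagnostics"
  )
}

#' @export
print.mi_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<mi_diagnostics> %d chains x %d retained iterations; max PSRF = %.4f (threshold %.3f): %s\n",
    x$n_chains, x$chain_length, max(x$psrf$psrf), x$threshold,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Draw the M completed datasets from a converged chain
#'
#' Continues the first chain for `post_burn_iterations` further iterations
#' and saves the completed dataset every
#' `floor(post_burn_iterations / n_imputations)` iterations, yielding
#' exactly M completed panel tables. Observed cells are carried through
#' untouched; imputed continuous values are clipped to their scale bounds
#' (not rounded to the Likert grid); imputed gender is rounded to {0, 1} and
#' imputed generation to the nearest category via its dummies.
#'
#' @param chains A `da_chains` object.
#' @param config Optional [imputation_config()] override (defaults to the
#'   one carried by `chains`).
#' @param diagnostics Optional `mi_diagnostics`; when supplied and not
#'   converged, drawing stops unless `force = TRUE`.
#' @param force Logical; draw even from a non-converged chain (a warning is
#'   issued).
#' @return An object of class `mi_set`.
#' @export
draw_imputations <- function(chains, config = chains$config,
                             diagnostics = NULL, force = FALSE) {
  stopifnot(inherits(chains, "da_chains"))
  if (!is.null(diagnostics) && !diagnostics$converged) {
    if (!force) {
      abort(sprintf(
        "Chains not converged (max PSRF %.3f >= %.3f); pass force = TRUE to override.",
        max(diagnostics$psrf$psrf), diagnostics$threshold
      ))
    }
    warn("Drawing imputations from a non-converged chain (force = TRUE).")
  }
  m_imp <- config$n_imputations
  spacing <- config$post_burn_iterations %/% m_imp
  if (spacing < 1) {
    abort("Requested number of imputations exceeds the available spacing.")
  }
  ch1 <- chains$chains[[1]]
  m <- chains$matrix
  y0 <- ch1$y
  if (is.null(y0)) {
    y0 <- m
    for (j in seq_len(ncol(m))) y0[is.na(m[, j]), j] <- chains$col_means[j]
  }
  pats <- chains$patterns
  save_iters <- as.integer(spacing * seq_len(m_imp))
  seed_d <- if (!is.null(config$seed)) child_seed(config$seed, "draws")
  res <- with_seed(seed_d, {
    da_gibbs_cpp(y0, lapply(pats, `[[`, "rows"), lapply(pats, `[[`, "mis"),
                 lapply(pats, `[[`, "obs"), max(save_iters), 0L,
                 save_iters, ch1$mu, ch1$sigma, config$ridge)
  })
  tables <- lapply(res$saves, function(yc) {
    reconstruct_panel(chains$table, yc, colnames(m), chains$variables)
  })
  structure(
    list(
      tables = tables, diagnostics = diagnostics, config = config,
      variables = chains$variables, engine = "joint_da"
    ),
    class = "mi_set"
  )
}

# Fill imputed cells of the original table from a completed matrix, clipping
# to schema bounds and rounding imputed demographics to valid categories.
reconstruct_panel <- function(tbl, completed, mat_cols, variables) {
  schema <- panel_schema(tbl)
  df <- tibble::as_tibble(tbl)
  for (v in variables) {
    if (v == "generation") {
      miss <- is.na(df$generation)
      if (any(miss)) {
        g2 <- completed[miss, match("gen2", mat_cols)]
        g3 <- completed[miss, match("gen3", mat_cols)]
        cat3 <- cbind(1 - g2 - g3, g2, g3)
        df$generation[miss] <- max.col(cat3, ties.method = "first")
      }
      next
    }
    j <- match(v, mat_cols)
    if (is.na(j)) next
    miss <- is.na(df[[v]])
    if (!any(miss)) next
    vals <- completed[miss, j]
    row <- schema[schema$variable == v, ]
    if (identical(v, "gender")) {
      vals <- clip(round(vals), 0, 1)
    } else if (nrow(row) && !is.na(row$lo)) {
      vals <- clip(vals, row$lo, row$hi)
    }
    df[[v]][miss] <- vals
  }
  panel_table(df, schema = schema)
}

#' Multiply impute an incomplete panel
#'
#' Convenience wrapper: runs the burn-in chains, checks the PSRF gate, and
#' draws the M completed datasets. `engine = "fcs"` substitutes a
#' fully-conditional-specification engine (per-variable Bayesian normal
#' regressions) used in the sensitivity grid.
#'
#' @param tbl A [panel_table()].
#' @param config An [imputation_config()].
#' @param engine `"joint_da"` (default) or `"fcs"`.
#' @param force Draw even if the PSRF gate fails.
#' @return An `mi_set`: `tables` (list of M completed panel tables),
#'   `diagnostics`, `config`, `engine`.
#' @export
impute_panel <- function(tbl, config = imputation_config(),
                         engine = c("joint_da", "fcs"), force = FALSE) {
  engine <- match.arg(engine)
  if (engine == "fcs") {
    return(impute_panel_fcs(tbl, config))
  }
  chains <- run_data_augmentation(tbl, config)
  diagnostics <- if (config$n_chains >= 2 && config$burn_in > 0) {
    compute_psrf(chains)
  }
  draw_imputations(chains, config, diagnostics = diagnostics, force = force)
}

#' @export
print.mi_set <- function(x, ...) {
  cat(sprintf("<mi_set> %d imputations via %s engine\n",
              length(x$tables), x$engine))
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

# Fully-conditional-specification engine: initialize missing cells by
# sampling observed values, then cycle Bayesian normal regressions of each
# incomplete variable on all others, drawing (sigma^2, beta) from their
# posterior and imputing with noise. Independent short chains per imputation.
impute_panel_fcs <- function(tbl, config = imputation_config(), cycles = 10) {
  variables <- config$variables %||%
    intersect(default_imputation_vars(panel_schema(tbl)), names(tbl))
  info <- build_impute_matrix(tbl, variables)
  m <- info$matrix
  miss <- is.na(m)
  incomplete <- which(colSums(miss) > 0)
  tables <- vector("list", config$n_imputations)
  for (imp in seq_len(config$n_imputations)) {
    seed_i <- if (!is.null(config$seed)) child_seed(config$seed, paste0("fcs", imp))
    yc <- with_seed(seed_i, {
      yc <- m
      for (j in seq_len(ncol(m))) {
        obs <- m[!miss[, j], j]
        yc[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
      }
      for (cy in seq_len(cycles)) {
        for (j in incomplete) {
          x <- cbind(1, yc[, -j, drop = FALSE])
          oj <- !miss[, j]
          xo <- x[oj, , drop = FALSE]
          yo <- yc[oj, j]
          qr_x <- qr(xo)
          if (qr_x$rank < ncol(xo)) next
          beta_hat <- qr.coef(qr_x, yo)
          res <- yo - drop(xo %*% beta_hat)
          df_r <- max(length(yo) - ncol(xo), 1)
          sigma2 <- sum(res^2) / stats::rchisq(1, df_r)
          rinv <- backsolve(qr.R(qr_x), diag(ncol(xo)))
          beta <- beta_hat + drop(rinv %*% rnorm(ncol(xo))) * sqrt(sigma2)
          xm <- x[miss[, j], , drop = FALSE]
          yc[miss[, j], j] <- drop(xm %*% beta) + rnorm(nrow(xm), 0, sqrt(sigma2))
        }
      }
      yc
    })
    tables[[imp]] <- reconstruct_panel(tbl, yc, colnames(m), variables)
  }
  structure(
    list(tables = tables, diagnostics = NULL, config = config,
         variables = variables, engine = "fcs"),
    class = "mi_set"
  )
}
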