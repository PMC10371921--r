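eq_names <- c("m1", "m2", "m3", "y", "total")

# Expand covariate names to numeric model columns (generation -> dummies).
expand_covariates <- function(df, covariates) {
  cols <- character(0)
  for (v in covariates) {
    if (v == "generation") {
      df$gen2 <- as.numeric(df$generation == 2)
      df$gen3 <- as.numeric(df$generation == 3)
      cols <- c(cols, "gen2", "gen3")
    } else {
      cols <- c(cols, v)
    }
  }
  list(df = df, cols = cols)
}

equation_terms <- function(cov_cols = character()) {
  u <- c("u1_t1", "u2_t1", "u3_t1", "u4_t1")
  list(
    m1 = list(y = "m1_t2", x = c("x_t1", u, cov_cols)),
    m2 = list(y = "m2_t2", x = c("x_t1", u, cov_cols)),
    m3 = list(y = "m3_t2", x = c("x_t1", u, cov_cols)),
    y = list(y = "y_t2", x = c("x_t1", "m1_t2", "m2_t2", "m3_t2", u, cov_cols)),
    total = list(y = "y_t2", x = c("x_t1", u, cov_cols))
  )
}

#' Fit the five-equation OLS path system on a completed dataset
#'
#' Ordinary least squares with classical standard errors for the parallel
#' multiple mediation system: each T2 mediator regressed on the T1 predictor
#' and the four lagged covariates, the T2 outcome regressed on the
#' predictor, the three mediators and the lagged covariates, and the
#' total-effect equation (outcome on predictor and lagged covariates,
#' without the mediators). Optional demographic covariates are appended to
#' every equation so the total-effect decomposition identity is preserved.
#'
#' @param data A completed [panel_table()] or data frame: no missing cells
#'   among the analysis variables (and requested covariates).
#' @param covariates Extra covariates appended to all equations, any of
#'   `"age"`, `"gender"`, `"generation"`.
#' @param include_total Fit the total-effect equation as well (default TRUE).
#' @return An object of class `path_fit`; see [tidy.path_fit()].
#' @export
fit_path_model <- function(data, covariates = character(), include_total = TRUE) {
  df <- as.data.frame(data)
  ex <- expand_covariates(df, covariates)
  df <- ex$df
  eqs <- equation_terms(ex$cols)
  if (!include_total) eqs$total <- NULL
  used <- unique(unlist(lapply(eqs, function(e) c(e$y, e$x))))
  absent <- setdiff(used, names(df))
  if (length(absent)) {
    abort(sprintf("Variables absent from the data: %s", paste(absent, collapse = ", ")))
  }
  if (anyNA(df[used])) {
    abort("Missing cells present among the analysis variables; impute first.")
  }
  n <- nrow(df)
  out <- vector("list", length(eqs))
  for (i in seq_along(eqs)) {
    e <- eqs[[i]]
    if (n <= length(e$x) + 1) abort("More regressors than observations.")
    f <- stats::as.formula(paste(e$y, "~", paste(e$x, collapse = " + ")))
    fit <- lm(f, data = df)
    cf <- coef(fit)
    if (anyNA(cf)) {
      abort(sprintf("Rank-deficient design in equation '%s'.", names(eqs)[i]))
    }
    sm <- suppressWarnings(summary(fit))$coefficients
    out[[i]] <- tibble::tibble(
      equation = names(eqs)[i],
      term = rownames(sm),
      estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
      statistic = unname(sm[, 3]), df = fit$df.residual,
      p.value = unname(sm[, 4])
    )
  }
  structure(
    list(
      coefficients = dplyr::bind_rows(out), n = n,
      covariates = covariates, cov_cols = ex$cols,
      include_total = include_total
    ),
    class = "path_fit"
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> %d equations on n = %d\n",
              length(unique(x$coefficients$equation)), x$n))
  print(indirect_effects(x))
  invisible(x)
}

coef_of <- function(coefs, equation, term) {
  v <- coefs$estimate[coefs$equation == equation & coefs$term == term]
  if (length(v) != 1) NA_real_ else v
}

#' Specific, total indirect, direct, and total effects from a fitted system
#'
#' The specific indirect effect through mediator j is the product
#' \eqn{a_j b_j}; the total indirect effect is their sum (exactly); the
#' direct effect is \eqn{c'} and the total effect \eqn{c_1} from the
#' mediator-free equation.
#'
#' @param fit A [fit_path_model()] result, or its coefficients tibble.
#' @return A tibble with columns `effect` and `estimate`.
#' @export
indirect_effects <- function(fit) {
  coefs <- if (inherits(fit, "path_fit")) fit$coefficients else fit
  a <- vapply(c("m1", "m2", "m3"), function(e) coef_of(coefs, e, "x_t1"), numeric(1))
  b <- vapply(c("m1_t2", "m2_t2", "m3_t2"), function(t) coef_of(coefs, "y", t), numeric(1))
  indirect_from_paths(
    a = a, b = b,
    cprime = coef_of(coefs, "y", "x_t1"),
    total = coef_of(coefs, "total", "x_t1")
  )
}

#' Indirect effects from explicit path coefficients
#'
#' @param a Length-3 vector of predictor-to-mediator paths.
#' @param b Length-3 vector of mediator-to-outcome paths.
#' @param cprime Direct effect (optional).
#' @param total Total effect (optional).
#' @return A tibble with columns `effect` and `estimate`.
#' @export
#' @examples
#' indirect_from_paths(a = c(0.019, 0.032, 0.005), b = c(0.001, 0.117, 0.011))
indirect_from_paths <- function(a, b, cprime = NA_real_, total = NA_real_) {
  stopifnot(length(a) == 3, length(b) == 3)
  specific <- as.numeric(a) * as.numeric(b)
  tibble::tibble(
    effect = c("indirect_m1", "indirect_m2", "indirect_m3",
               "total_indirect", "direct", "total"),
    estimate = c(specific, sum(specific), cprime, total)
  )
}

# --- fast machinery shared with the bootstrap ------------------------------

# Numeric matrix of the modelling columns of a completed panel.
path_matrix <- function(data, cov_cols = character()) {
  df <- as.data.frame(data)
  if (any(c("gen2", "gen3") %in% cov_cols) && !"gen2" %in% names(df)) {
    df$gen2 <- as.numeric(df$generation == 2)
    df$gen3 <- as.numeric(df$generation == 3)
  }
  vars <- c("x_t1", "m1_t2", "m2_t2", "m3_t2", "y_t2",
            "u1_t1", "u2_t1", "u3_t1", "u4_t1", cov_cols)
  m <- as.matrix(df[vars])
  storage.mode(m) <- "double"
  m
}

# Equation specs (1-based column indices into path_matrix) for the C++
# bootstrap core. Extracted coefficients per replicate, in order:
# a1, a2, a3, cprime, b1, b2, b3 (and c1 when include_total).
boot_eq_spec <- function(cov_cols = character(), include_total = FALSE) {
  base <- c("x_t1", "m1_t2", "m2_t2", "m3_t2", "y_t2",
            "u1_t1", "u2_t1", "u3_t1", "u4_t1")
  allv <- c(base, cov_cols)
  idx <- function(v) match(v, allv)
  u <- c("u1_t1", "u2_t1", "u3_t1", "u4_t1")
  xu <- idx(c("x_t1", u, cov_cols))
  eqs <- list(
    list(cols = xu, ycol = idx("m1_t2"), take = 2L),
    list(cols = xu, ycol = idx("m2_t2"), take = 2L),
    list(cols = xu, ycol = idx("m3_t2"), take = 2L),
    list(cols = idx(c("x_t1", "m1_t2", "m2_t2", "m3_t2", u, cov_cols)),
         ycol = idx("y_t2"), take = c(2L, 3L, 4L, 5L))
  )
  if (include_total) {
    eqs <- c(eqs, list(list(cols = xu, ycol = idx("y_t2"), take = 2L)))
  }
  eqs
}

# Point fits of the equation system without SEs (used inside
# bootstrap-then-imputation replicates).
fit_paths_point <- function(m, eqs) {
  unlist(lapply(eqs, function(e) {
    x <- cbind(1, m[, e$cols, drop = FALSE])
    fit <- stats::.lm.fit(x, m[, e$ycol])
    if (fit$rank < ncol(x)) stop("rank-deficient design", call. = FALSE)
    fit$coefficients[e$take]
  }))
}

draw_col_names <- function(include_total = FALSE) {
  c("a1", "a2", "a3", "cprime", "b1", "b2", "b3", if (include_total) "c1")
}

# Map raw coefficient draws (columns a1,a2,a3,cprime,b1,b2,b3) to effect
# draws (3 specific products, their sum, the direct effect).
effect_draws <- function(raw) {
  cbind(
    indirect_m1 = raw[, "a1"] * raw[, "b1"],
    indirect_m2 = raw[, "a2"] * raw[, "b2"],
    indirect_m3 = raw[, "a3"] * raw[, "b3"],
    total_indirect = raw[, "a1"] * raw[, "b1"] + raw[, "a2"] * raw[, "b2"] +
      raw[, "a3"] * raw[, "b3"],
    direct = raw[, "cprime"]
  )
}
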