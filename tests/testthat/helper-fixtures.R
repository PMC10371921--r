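# Shared fixtures: small synthetic panels and fast chain settings.

# One default config per scale, built lazily and memoised: building a
# simulation_config runs the copula/residual calibration, so reuse it.
fixture_env <- new.env(parent = emptyenv())

default_config <- function(n, ...) {
  key <- paste0("cfg_", n, "_", rlang::hash(list(...)))
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulation_config(n = n, ...)
  }
  fixture_env[[key]]
}

# Fully observed panel at the default study conditions.
complete_panel <- function(n, seed = 101, ...) {
  generate_panel(default_config(n, ...), seed = seed)
}

# Panel with the default 28-38% MAR missingness imposed.
incomplete_panel <- function(n, seed = 101, ...) {
  cfg <- default_config(n, ...)
  impose_missingness(generate_panel(cfg, seed = seed), cfg,
                     seed = seed + 1)
}

# Chain settings sized for tests: data augmentation for a joint normal of
# ~17 variables mixes in tens of iterations, so short chains suffice here.
quick_imp_config <- function(M = 5, seed = 7, burn_in = 300,
                             post = max(10 * M, M), n_chains = 1) {
  imputation_config(
    burn_in = burn_in, post_burn_iterations = post, n_imputations = M,
    n_chains = n_chains, seed = seed
  )
}

# A tiny hand-buildable panel for IO and descriptive tests.
hand_panel <- function() {
  panel_table(tibble::tibble(
    subject_id = c("a", "b", "c"),
    x_t1 = c(1, 2, 3),
    u1_t1 = c(1, 3, 2),
    y_t2 = c(2, NA, 3.5)
  ))
}

# Pseudo-true (induced) path estimand of a config: complete-data OLS at
# large n. This is the oracle recovery tests compare against, since
# bound-censoring of scores near scale ceilings attenuates the latent
# structural coefficients.
pseudo_true_paths <- function(cfg, n = 120000, seed = 4242) {
  key <- paste0("oracle_", substr(rlang::hash(cfg[c(
    "true_a", "true_b", "true_cprime", "u_coefs", "y_u_coefs",
    "intercepts", "resid_sds"
  )]), 1, 12), "_", n)
  if (is.null(fixture_env[[key]])) {
    big <- cfg
    big$n <- as.integer(n)
    f <- fit_path_model(generate_panel(big, seed = seed))
    cf <- f$coefficients
    fixture_env[[key]] <- list(
      a = vapply(c("m1", "m2", "m3"),
                 function(e) cf$estimate[cf$equation == e & cf$term == "x_t1"],
                 numeric(1)),
      b = vapply(c("m1_t2", "m2_t2", "m3_t2"),
                 function(t) cf$estimate[cf$equation == "y" & cf$term == t],
                 numeric(1)),
      cprime = cf$estimate[cf$equation == "y" & cf$term == "x_t1"]
    )
  }
  fixture_env[[key]]
}

# Minimal hand-made path_fit for pooling fixtures.
fake_fit <- function(estimate, se = 1, df = 100, equation = "m1",
                     term = "x_t1") {
  structure(
    list(
      coefficients = tibble::tibble(
        equation = equation, term = term, estimate = estimate,
        std.error = se, statistic = estimate / se, df = df,
        p.value = 2 * stats::pt(-abs(estimate / se), df)
      ),
      n = df + 6, covariates = character(), cov_cols = character(),
      include_total = FALSE
    ),
    class = "path_fit"
  )
}
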