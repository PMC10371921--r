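#' Descriptive tables for a panel
#'
#' Complete-case descriptives (mean, SD) of the nine analysis variables,
#' the per-variable missingness percentage computed on the full table, and
#' pairwise-complete bivariate correlations within the complete-case subset
#' with per-pair df and two-sided p, starred at the 0.05 / 0.01 levels.
#' A variable with zero variance gets an `NA` correlation and a note.
#'
#' @param tbl A [panel_table()].
#' @param vars Variables to describe; defaults to the analysis variables.
#' @return A list of class `panel_description`: `descriptives` tibble,
#'   `correlations` tibble (lower triangle, long form), `n_complete`.
#' @export
describe_panel <- function(tbl, vars = NULL) {
  schema <- panel_schema(tbl)
  vars <- vars %||% intersect(analysis_vars(schema), names(tbl))
  df_all <- as.data.frame(tbl)[vars]
  cc <- df_all[complete.cases(df_all), , drop = FALSE]
  desc <- tibble::tibble(
    variable = vars,
    mean = unname(vapply(cc, mean, numeric(1))),
    sd = unname(vapply(cc, sd, numeric(1))),
    pct_missing = unname(vapply(df_all, function(v) 100 * mean(is.na(v)),
                                numeric(1)))
  )
  pairs <- utils::combn(vars, 2)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    v1 <- cc[[pairs[1, i]]]
    v2 <- cc[[pairs[2, i]]]
    ok <- stats::complete.cases(v1, v2)
    n_pair <- sum(ok)
    if (n_pair < 3 || sd(v1[ok]) == 0 || sd(v2[ok]) == 0) {
      inform(sprintf("Correlation undefined for %s ~ %s (degenerate variance).",
                     pairs[1, i], pairs[2, i]))
      rows[[i]] <- tibble::tibble(
        var1 = pairs[1, i], var2 = pairs[2, i], r = NA_real_,
        df = NA_real_, p.value = NA_real_, stars = ""
      )
      next
    }
    r <- cor(v1[ok], v2[ok])
    df_pair <- n_pair - 2
    tstat <- r * sqrt(df_pair / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df_pair)
    rows[[i]] <- tibble::tibble(
      var1 = pairs[1, i], var2 = pairs[2, i], r = r, df = df_pair,
      p.value = p, stars = if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    )
  }
  structure(
    list(
      descriptives = desc, correlations = dplyr::bind_rows(rows),
      n_complete = nrow(cc)
    ),
    class = "panel_description"
  )
}

#' @export
print.panel_description <- function(x, ...) {
  cat(sprintf("<panel_description> complete cases: n = %d\n", x$n_complete))
  print(x$descriptives)
  invisible(x)
}

#' Configuration of the full mediation pipeline
#'
#' Exactly one of `input` (a [panel_table()] or a CSV path) and `simulation`
#' (a [simulation_config()]) must be supplied.
#'
#' @param input A [panel_table()] or CSV path.
#' @param simulation A [simulation_config()]; the pipeline then generates
#'   the panel and imposes the configured missingness.
#' @param imputation An [imputation_config()].
#' @param B Bootstrap replicates.
#' @param orders Character vector of bootstrap nesting orders to run.
#' @param covariates Extra covariates for all equations.
#' @param level Confidence level.
#' @param out_dir Output directory for tables, manifest and log (`NULL`:
#'   nothing written).
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Log stage progress.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            imputation = imputation_config(),
                            B = 1000, orders = "imputation_then_bootstrap",
                            covariates = character(), level = 0.95,
                            out_dir = NULL, seed = 1L, verbose = TRUE) {
  if (is.null(input) == is.null(simulation)) {
    abort("Supply exactly one of `input` and `simulation`.")
  }
  stopifnot(all(orders %in% c("imputation_then_bootstrap",
                              "bootstrap_then_imputation")))
  structure(
    list(input = input, simulation = simulation, imputation = imputation,
         B = as.integer(B), orders = orders, covariates = covariates,
         level = level, out_dir = out_dir, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

pipe_log <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  if (state$verbose) inform(line)
  if (!is.null(state$log_path)) cat(line, "\n", file = state$log_path,
                                    append = TRUE, sep = "")
  invisible(NULL)
}

#' Run the full mediation pipeline
#'
#' Stages: data acquisition (read or simulate + mask) -> descriptive tables
#' -> multiple imputation with the PSRF convergence gate -> per-imputation
#' path fits and Rubin's-rules pooling -> percentile bootstrap intervals in
#' the requested nesting order(s). When `out_dir` is set, writes the
#' descriptive tables, the pooled regression table, one indirect-effects
#' table per order, a JSON run manifest (seeds, configs, PSRF values,
#' redraw counts), and a plain-text log; re-running with the same master
#' seed reproduces every output byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param force Proceed past a failed PSRF gate (logged).
#' @return A list of class `mediation_results` with elements `data`,
#'   `description`, `imputations`, `pooled`, `boot` (one entry per order),
#'   and `manifest`.
#' @export
run_mediation_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  state <- list(verbose = config$verbose, log_path = NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    state$log_path <- file.path(config$out_dir, "pipeline.log")
    if (file.exists(state$log_path)) file.remove(state$log_path)
  }
  stage <- function(name, expr) {
    pipe_log(state, "start %s", name)
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    pipe_log(state, "end %s", name)
    out
  }

  tbl <- stage("data", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      complete <- generate_panel(sim, seed = child_seed(config$seed, "generate"))
      impose_missingness(complete, sim, seed = child_seed(config$seed, "mask"))
    } else if (is.character(config$input)) {
      read_panel(config$input)
    } else {
      panel_table(config$input)
    }
  })

  description <- stage("descriptives", describe_panel(tbl))
  pipe_log(state, "complete cases: %d of %d", description$n_complete, nrow(tbl))

  imp_cfg <- config$imputation
  imp_cfg$seed <- child_seed(config$seed, "impute")
  mi <- stage("imputation", impute_panel(tbl, imp_cfg, force = force))
  if (!is.null(mi$diagnostics)) {
    pipe_log(state, "max PSRF = %.4f (threshold %.3f)",
             max(mi$diagnostics$psrf$psrf), mi$diagnostics$threshold)
  }

  fits <- stage("estimation",
                lapply(mi$tables, fit_path_model, covariates = config$covariates))
  pooled <- stage("pooling", pool_rubin(fits))

  boots <- list()
  for (ord in config$orders) {
    boots[[ord]] <- stage(paste0("bootstrap_", ord), {
      bootstrap_mediation(
        tbl, imp_config = imp_cfg, B = config$B, order = ord,
        level = config$level, covariates = config$covariates,
        seed = child_seed(config$seed, paste0("order_", ord)), mi_set = mi
      )
    })
    pipe_log(state, "%s: %d pooled draws, %d redraws", ord,
             boots[[ord]]$n_draws, boots[[ord]]$redraws)
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(
      generate = child_seed(config$seed, "generate"),
      mask = child_seed(config$seed, "mask"),
      impute = child_seed(config$seed, "impute"),
      orders = setNames(
        lapply(config$orders, function(o) child_seed(config$seed, paste0("order_", o))),
        config$orders
      )
    ),
    n = nrow(tbl), n_complete = description$n_complete,
    M = length(mi$tables), B = config$B, orders = config$orders,
    covariates = config$covariates, level = config$level,
    engine = mi$engine,
    psrf = if (!is.null(mi$diagnostics)) {
      list(max = max(mi$diagnostics$psrf$psrf),
           threshold = mi$diagnostics$threshold,
           converged = mi$diagnostics$converged)
    },
    redraws = lapply(boots, `[[`, "redraws")
  )

  if (!is.null(config$out_dir)) {
    stage("write_outputs", {
      readr::write_csv(description$descriptives,
                       file.path(config$out_dir, "descriptives.csv"))
      readr::write_csv(description$correlations,
                       file.path(config$out_dir, "correlations.csv"))
      write_path_table(pooled, file.path(config$out_dir, "path_estimates.csv"))
      for (ord in names(boots)) {
        write_indirect_table(
          boots[[ord]],
          file.path(config$out_dir, sprintf("indirect_effects_%s.csv", ord))
        )
      }
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  structure(
    list(data = tbl, description = description, imputations = mi,
         pooled = pooled, fits = fits, boot = boots, manifest = manifest,
         config = config),
    class = "mediation_results"
  )
}

#' @export
print.mediation_results <- function(x, ...) {
  cat(sprintf("<mediation_results> n = %d (complete %d), M = %d, B = %d\n",
              nrow(x$data), x$description$n_complete,
              length(x$imputations$tables), x$config$B))
  for (ord in names(x$boot)) {
    cat("--", ord, "--\n")
    print(x$boot[[ord]]$ci)
  }
  invisible(x)
}

#' Run a sensitivity grid of model variants
#'
#' Each variant combines an imputation engine (`joint_da`, `fcs`, or
#' `complete_case`), a bootstrap nesting order, a covariate set, and a
#' demographics flag, and is run at (typically reduced) M and B. A variant
#' failure is recorded and the grid continues. The concordance summary
#' counts the variants flagging each effect significant.
#'
#' @param config A [pipeline_config()] providing the data source, base
#'   imputation settings, seed and level.
#' @param engines Imputation engines to cross.
#' @param orders Bootstrap nesting orders to cross.
#' @param covariate_sets Named list of covariate character vectors.
#' @param M,B Per-variant imputation count and bootstrap replicates.
#' @return An object of class `sensitivity_grid`: per-variant results and
#'   a concordance summary.
#' @export
run_sensitivity_grid <- function(config,
                                 engines = c("joint_da", "fcs", "complete_case"),
                                 orders = c("imputation_then_bootstrap",
                                            "bootstrap_then_imputation"),
                                 covariate_sets = list(none = character()),
                                 M = 10, B = 200) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- expand.grid(engine = engines, order = orders,
                      covariate_set = names(covariate_sets),
                      stringsAsFactors = FALSE)
  if (nrow(grid) < 2) abort("A sensitivity grid needs at least 2 variants.")

  tbl <- if (!is.null(config$simulation)) {
    complete <- generate_panel(config$simulation,
                               seed = child_seed(config$seed, "generate"))
    impose_missingness(complete, config$simulation,
                       seed = child_seed(config$seed, "mask"))
  } else if (is.character(config$input)) {
    read_panel(config$input)
  } else {
    panel_table(config$input)
  }

  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    seed_v <- child_seed(config$seed, paste0("variant", i))
    covs <- covariate_sets[[v$covariate_set]]
    results[[i]] <- tryCatch({
      if (v$engine == "complete_case") {
        cc <- tibble::as_tibble(tbl)
        keep <- complete.cases(as.data.frame(cc)[intersect(
          analysis_vars(panel_schema(tbl)), names(cc))])
        cc_tbl <- panel_table(cc[keep, ], schema = panel_schema(tbl))
        mi <- structure(
          list(tables = list(cc_tbl), diagnostics = NULL,
               config = imputation_config(n_imputations = 1, burn_in = 0,
                                          post_burn_iterations = 1, n_chains = 1),
               variables = NULL, engine = "complete_case"),
          class = "mi_set"
        )
        # a single completed table needs all its draws from the bootstrap
        boot <- bootstrap_mediation(cc_tbl, B = max(B, 200),
                                    order = "imputation_then_bootstrap",
                                    level = config$level, covariates = covs,
                                    seed = seed_v, mi_set = mi)
      } else {
        imp_cfg <- config$imputation
        imp_cfg$n_imputations <- as.integer(M)
        imp_cfg$post_burn_iterations <-
          max(imp_cfg$post_burn_iterations, as.integer(M))
        imp_cfg$seed <- child_seed(seed_v, "impute")
        mi <- if (v$engine == "fcs") {
          impute_panel(tbl, imp_cfg, engine = "fcs")
        } else {
          impute_panel(tbl, imp_cfg)
        }
        boot <- bootstrap_mediation(tbl, imp_config = imp_cfg, B = B,
                                    order = v$order, level = config$level,
                                    covariates = covs, seed = seed_v,
                                    mi_set = mi)
      }
      dplyr::mutate(boot$ci, engine = v$engine, order = v$order,
                    covariate_set = v$covariate_set, seed = seed_v,
                    variant = i, .before = 1)
    }, error = function(e) {
      warn(sprintf("Variant %d (%s/%s/%s) failed: %s", i, v$engine, v$order,
                   v$covariate_set, conditionMessage(e)))
      tibble::tibble(variant = i, engine = v$engine, order = v$order,
                     covariate_set = v$covariate_set, seed = seed_v,
                     effect = NA_character_, estimate = NA_real_,
                     lower = NA_real_, upper = NA_real_,
                     level = config$level, significant = NA)
    })
  }
  all_ci <- dplyr::bind_rows(results)
  ok <- !is.na(all_ci$effect)
  concordance <- all_ci[ok, ] |>
    dplyr::group_by(.data$effect) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_significant = sum(.data$significant),
      .groups = "drop"
    )
  structure(
    list(grid = tibble::as_tibble(grid), results = all_ci,
         concordance = concordance, n_failed = sum(!ok)),
    class = "sensitivity_grid"
  )
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %d variants\n", nrow(x$grid)))
  print(x$concordance)
  invisible(x)
}
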