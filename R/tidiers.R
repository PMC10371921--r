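#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the coefficients of a fitted path system
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `equation`, `term`,
#'   `estimate`, `std.error`, `statistic`, `df`, `p.value`.
#' @export
tidy.path_fit <- function(x, ...) x$coefficients

#' One-row summary of a fitted path system
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_equations`, `total_indirect`, `direct`.
#' @export
glance.path_fit <- function(x, ...) {
  eff <- indirect_effects(x)
  tibble::tibble(
    n = x$n,
    n_equations = length(unique(x$coefficients$equation)),
    total_indirect = eff$estimate[eff$effect == "total_indirect"],
    direct = eff$estimate[eff$effect == "direct"]
  )
}

#' Tidy Rubin-pooled coefficients
#'
#' @param x An `mi_pool`.
#' @param ... Unused.
#' @return The pooled estimates tibble.
#' @export
tidy.mi_pool <- function(x, ...) x$estimates

#' One-row summary of a pooled fit
#'
#' @param x An `mi_pool`.
#' @param ... Unused.
#' @return Tibble with `m`, `n`, `max_fmi`.
#' @export
glance.mi_pool <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, max_fmi = max(x$estimates$fmi))
}

#' Tidy bootstrap mediation intervals
#'
#' @param x A `boot_mediation`.
#' @param ... Unused.
#' @return The per-effect CI tibble.
#' @export
tidy.boot_mediation <- function(x, ...) x$ci

#' One-row summary of a bootstrap mediation run
#'
#' @param x A `boot_mediation`.
#' @param ... Unused.
#' @return Tibble with `order`, `M`, `B`, `n_draws`, `redraws`, `level`.
#' @export
glance.boot_mediation <- function(x, ...) {
  tibble::tibble(order = x$order, M = x$M, B = x$B, n_draws = x$n_draws,
                 redraws = x$redraws, level = x$level)
}

#' Tidy convergence diagnostics
#'
#' @param x An `mi_diagnostics`.
#' @param ... Unused.
#' @return The per-parameter PSRF tibble.
#' @export
tidy.mi_diagnostics <- function(x, ...) x$psrf

#' One-row summary of convergence diagnostics
#'
#' @param x An `mi_diagnostics`.
#' @param ... Unused.
#' @return Tibble with `max_psrf`, `threshold`, `converged`,
#'   `chain_length`, `n_chains`.
#' @export
glance.mi_diagnostics <- function(x, ...) {
  tibble::tibble(max_psrf = max(x$psrf$psrf), threshold = x$threshold,
                 converged = x$converged, chain_length = x$chain_length,
                 n_chains = x$n_chains)
}
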