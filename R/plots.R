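#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_hline geom_vline geom_line geom_col facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Forest plot of indirect-effect percentile intervals
#'
#' @param object A `boot_mediation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boot_mediation <- function(object, ...) {
  d <- object$ci
  d$effect <- factor(d$effect, levels = rev(mediation_effects))
  ggplot(d, aes(x = .data$estimate, y = .data$effect)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lower, xmax = .data$upper), height = 0.2) +
    geom_point(aes(colour = .data$significant), size = 2) +
    labs(
      x = sprintf("Estimate (%d%% percentile bootstrap CI)",
                  round(100 * object$level)),
      y = NULL,
      title = sprintf("Indirect effects (%s, %d pooled draws)",
                      object$order, object$n_draws)
    ) +
    theme_minimal()
}

#' PSRF diagnostic plot
#'
#' Per-parameter potential scale reduction factors with the convergence
#' threshold.
#'
#' @param object An `mi_diagnostics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_diagnostics <- function(object, ...) {
  d <- object$psrf
  d$parameter <- factor(d$parameter, levels = d$parameter)
  ggplot(d, aes(x = .data$psrf, y = .data$parameter)) +
    geom_vline(xintercept = object$threshold, linetype = 2, colour = "red") +
    geom_point() +
    labs(x = "Potential scale reduction factor", y = NULL,
         title = sprintf("Gelman-Rubin diagnostics (%d chains x %d iterations)",
                         object$n_chains, object$chain_length)) +
    theme_minimal()
}

#' Coefficient plot of a fitted or pooled path system
#'
#' Dot-and-whisker display (estimate +/- 1.96 SE) of every coefficient,
#' faceted by equation.
#'
#' @param object A `path_fit` or `mi_pool`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.path_fit <- function(object, ...) {
  d <- if (inherits(object, "mi_pool")) object$estimates else object$coefficients
  d <- d[d$term != "(Intercept)", ]
  ggplot(d, aes(x = .data$estimate, y = .data$term)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                       xmax = .data$estimate + 1.96 * .data$std.error),
                   height = 0.2) +
    geom_point() +
    facet_wrap(~equation, scales = "free_y") +
    labs(x = "Coefficient (+/- 1.96 SE)", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.mi_pool <- autoplot.path_fit

#' Sensitivity-grid interval plot
#'
#' Percentile intervals for each effect across all grid variants.
#'
#' @param object A `sensitivity_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  d <- object$results[!is.na(object$results$effect), ]
  d$variant_label <- sprintf("%s / %s / %s", d$engine, d$order, d$covariate_set)
  ggplot(d, aes(x = .data$estimate, y = .data$variant_label)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$lower, xmax = .data$upper), height = 0.2) +
    geom_point(aes(colour = .data$significant), size = 1.5) +
    facet_wrap(~effect, scales = "free_x") +
    labs(x = "Estimate (percentile CI)", y = NULL) +
    theme_minimal()
}
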