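#' Define a multi-item Likert scale
#'
#' A scale definition records how a construct is measured: how many items,
#' the response bounds, which items are negatively worded (and must be
#' recoded before averaging), and the reliability the instrument is known to
#' attain (used as a calibration target when simulating item-level data).
#'
#' @param name Scale name.
#' @param item_count Number of items (positive integer).
#' @param response_min,response_max Bounds of the response options.
#' @param reverse_items Integer indices of negatively worded items, recoded
#'   as `min + max - v` before averaging.
#' @param target_alpha Cronbach's alpha the instrument attains, in `[0, 1]`.
#' @return An object of class `scale_definition`.
#' @export
#' @examples
#' scale_definition("self_esteem", 10, 1, 4,
#'   reverse_items = c(2, 5, 6, 8, 9), target_alpha = 0.81
#' )
scale_definition <- function(name, item_count, response_min, response_max,
                             reverse_items = integer(), target_alpha = NA_real_) {
  stopifnot(
    is.character(name), length(name) == 1,
    is_scalar_number(item_count), item_count >= 1,
    is_scalar_number(response_min), is_scalar_number(response_max)
  )
  if (response_min >= response_max) {
    abort("`response_min` must be strictly less than `response_max`.")
  }
  reverse_items <- as.integer(reverse_items)
  if (length(reverse_items) &&
      (any(reverse_items < 1) || any(reverse_items > item_count))) {
    abort("`reverse_items` must be a subset of 1..item_count.")
  }
  if (!is.na(target_alpha) && (target_alpha < 0 || target_alpha > 1)) {
    abort("`target_alpha` must lie in [0, 1].")
  }
  structure(
    list(
      name = name, item_count = as.integer(item_count),
      response_min = response_min, response_max = response_max,
      reverse_items = reverse_items, target_alpha = target_alpha
    ),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf(
    "<scale_definition> %s: %d items on [%g, %g]%s%s\n",
    x$name, x$item_count, x$response_min, x$response_max,
    if (length(x$reverse_items)) {
      sprintf(", reversed: %s", paste(x$reverse_items, collapse = ","))
    } else "",
    if (!is.na(x$target_alpha)) sprintf(", alpha = %.2f", x$target_alpha) else ""
  ))
  invisible(x)
}

#' Instrument definitions for the two-wave ethnic-identity panel design
#'
#' The default battery: a four-item 9-point scale for perceived impact of
#' the SB 1070 immigration law, five-item ethnic centrality, three-item
#' ethnic private regard, three-item ethnic public regard, and the ten-item
#' Rosenberg self-esteem scale (with its five negatively worded items
#' reverse-coded). Reliability targets are the values the instruments attain
#' in this population.
#'
#' @return Named list of [scale_definition()] objects.
#' @export
default_scales <- function() {
  list(
    sb1070 = scale_definition("sb1070", 4, 1, 9, target_alpha = 0.92),
    centrality = scale_definition("centrality", 5, 1, 5, target_alpha = 0.83),
    private_regard = scale_definition("private_regard", 3, 1, 5, target_alpha = 0.89),
    public_regard = scale_definition("public_regard", 3, 1, 4, target_alpha = 0.81),
    self_esteem = scale_definition("self_esteem", 10, 1, 4,
      reverse_items = c(2L, 5L, 6L, 8L, 9L), target_alpha = 0.81
    )
  )
}

#' Score a multi-item scale by the (prorated) item mean
#'
#' Reverse-coded items are recoded as `min + max - v`, then each subject's
#' score is the mean of their non-missing items, provided the fraction of
#' observed items reaches `min_prop_observed`; otherwise the score is
#' missing. With all items observed the score equals the plain arithmetic
#' mean and is invariant to item order.
#'
#' @param item_responses Numeric matrix or data frame, one row per subject,
#'   one column per item.
#' @param scale A [scale_definition()].
#' @param min_prop_observed Minimum fraction of items that must be observed
#'   for a prorated score (default 0.5).
#' @return Numeric vector of scale scores (NA where insufficient items).
#' @export
score_scale <- function(item_responses, scale, min_prop_observed = 0.5) {
  stopifnot(inherits(scale, "scale_definition"))
  m <- as.matrix(item_responses)
  storage.mode(m) <- "double"
  if (ncol(m) != scale$item_count) {
    abort(sprintf(
      "Item matrix has %d columns; scale '%s' declares %d items.",
      ncol(m), scale$name, scale$item_count
    ))
  }
  obs <- !is.na(m)
  bad <- m[obs] < scale$response_min | m[obs] > scale$response_max
  if (any(bad)) {
    abort(sprintf(
      "Observed item responses outside [%g, %g] for scale '%s'.",
      scale$response_min, scale$response_max, scale$name
    ))
  }
  if (length(scale$reverse_items)) {
    m[, scale$reverse_items] <-
      scale$response_min + scale$response_max - m[, scale$reverse_items]
  }
  prop <- rowMeans(obs)
  score <- rowMeans(m, na.rm = TRUE)
  score[prop < min_prop_observed | prop == 0] <- NA_real_
  score
}

#' Cronbach's alpha internal-consistency reliability
#'
#' Computed on listwise-complete rows as
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)}
#' where \eqn{s_j^2} are the item variances and \eqn{s_T^2} the variance of
#' the item sum.
#'
#' @param item_responses Numeric matrix or data frame of item responses.
#' @return Alpha in \eqn{(-\infty, 1]}.
#' @export
cronbach_alpha <- function(item_responses) {
  m <- as.matrix(item_responses)
  storage.mode(m) <- "double"
  if (ncol(m) < 2) abort("Cronbach's alpha needs at least 2 items.")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) abort("Cronbach's alpha needs at least 3 complete rows.")
  total_var <- var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    abort("Total-score variance is zero; alpha undefined.")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}
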