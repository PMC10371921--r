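#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats coef lm model.matrix pnorm pt qbeta qt quantile rbinom
#'   rnorm runif sd setNames var complete.cases plogis uniroot cor
#' @importFrom utils head
#' @import tibble
NULL

# Evaluate `code` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards. NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline (generation, masking, each
#' imputation chain, each bootstrap stream) draws its seed deterministically
#' from the master seed and a stage label, so any single stage can be
#' replayed in isolation.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes) * 97)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
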