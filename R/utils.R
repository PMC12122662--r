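#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive per-task sub-seeds from a root seed
#'
#' Sub-seeds are drawn once under the root seed so that downstream tasks
#' (e.g. PSA iterations) are independent of execution order.
#'
#' @param seed Root integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Monthly discount factors
#'
#' Annual rate `r` applied per month `t` as `(1 + r)^(-t/12)`.  The first
#' model year (cycles 1-12) carries trial-derived accruals and is not
#' discounted, so callers typically request factors for cycles 13 onward.
#'
#' @param t Integer vector of cycle indices (months).
#' @param rate_annual Annual discount rate (default 0.035).
#' @param start_month First month at which discounting applies (default 13).
#' @return Numeric vector of discount factors, 1 before `start_month`.
#' @export
discount_factor <- function(t, rate_annual = 0.035, start_month = 13L) {
  ifelse(t < start_month, 1, (1 + rate_annual)^(-t / 12))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
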