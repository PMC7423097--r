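# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all whole-SEK presentation values.
#' Base `round()` rounds half to even, which does not match how published
#' cost tables are rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a classed error so callers/tests can distinguish domain errors
# (bad values) from validation errors (bad structure/config).
abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("oacost_domain_error", "oacost_error")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("oacost_validation_error", "oacost_error")))
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort_domain(sprintf("`%s` must be a single non-negative number", what))
  }
  invisible(x)
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_domain(sprintf("`%s` must be a fraction in [0, 1]", what))
  }
  invisible(x)
}

# Truncated normal draws via inverse-CDF; degenerate sd gives the mean,
# clamped into [lower, upper].
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort_validation("`sd` must be non-negative")
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
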