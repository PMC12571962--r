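# Internal helpers shared across modules.

bb_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("bayesbold_", class), "bayesbold_error"), ...)
}

abort_format     <- function(message, ...) bb_abort(message, "format_error", ...)
abort_validation <- function(message, ...) bb_abort(message, "validation_error", ...)
abort_argument   <- function(message, ...) bb_abort(message, "argument_error", ...)
abort_config     <- function(message, ...) bb_abort(message, "config_error", ...)

#' @importFrom rlang %||%
NULL

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort_argument(sprintf("`%s` must be a finite number in [%s, %s].",
                           name, format(lower), format(upper)))
  }
  invisible(x)
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# multivariate log-beta: log B(a) = sum(lgamma(a)) - lgamma(sum(a))
lmbeta <- function(a) sum(lgamma(a)) - lgamma(sum(a))

# Derive independent child seeds from a root seed (kept below .Machine$integer.max).
child_seeds <- function(root_seed, n) {
  withr::with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}
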