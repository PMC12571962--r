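#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF -- a positive gamma density peaking around 5 s
#' minus a scaled gamma undershoot -- on a regular microtime grid. The kernel
#' is normalised so that its positive lobe sums to one, which makes the
#' convolved response to a sustained unit boxcar plateau near one signal unit.
#'
#' @param dt_s Microtime sampling step in seconds (`0 < dt_s <= 1`).
#' @param duration_s Kernel support in seconds.
#' @param peak_delay,peak_dispersion Shape of the positive lobe: the gamma
#'   density has shape `peak_delay / peak_dispersion` and scale
#'   `peak_dispersion` (defaults 6 s and 1 s, mode at 5 s).
#' @param undershoot_delay,undershoot_dispersion Same parameterisation for the
#'   undershoot lobe (defaults 16 s and 1 s).
#' @param peak_undershoot_ratio Ratio of peak to undershoot amplitude
#'   (default 6).
#'
#' @return An object of class `hrf_kernel`: a list with `values` (sampled
#'   kernel), `dt_s` and `duration_s`.
#' @examples
#' h <- canonical_hrf(0.125)
#' h$dt_s * (which.max(h$values) - 1) # peak near 5 s
#' @export
canonical_hrf <- function(dt_s = 0.125, duration_s = 32,
                          peak_delay = 6, peak_dispersion = 1,
                          undershoot_delay = 16, undershoot_dispersion = 1,
                          peak_undershoot_ratio = 6) {
  if (!is.numeric(dt_s) || length(dt_s) != 1L || !is.finite(dt_s) ||
      dt_s <= 0 || dt_s > 1) {
    abort_argument("`dt_s` must be a single number in (0, 1].")
  }
  assert_scalar_number(duration_s, "duration_s", lower = dt_s)
  t <- seq(0, by = dt_s, length.out = round(duration_s / dt_s))
  values <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                          scale = peak_dispersion) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / peak_undershoot_ratio
  values <- values / sum(values[values > 0])
  structure(
    list(values = values, dt_s = dt_s, duration_s = duration_s,
         params = list(peak_delay = peak_delay,
                       peak_dispersion = peak_dispersion,
                       undershoot_delay = undershoot_delay,
                       undershoot_dispersion = undershoot_dispersion,
                       peak_undershoot_ratio = peak_undershoot_ratio)),
    class = "hrf_kernel"
  )
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> dt = %g s, duration = %g s, peak at %.2f s\n",
              x$dt_s, x$duration_s, x$dt_s * (which.max(x$values) - 1)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hrf_kernel <- function(object, ...) {
  df <- tibble::tibble(
    time_s = seq(0, by = object$dt_s, length.out = length(object$values)),
    response = object$values
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "impulse response",
                  title = "Canonical hemodynamic response")
}
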