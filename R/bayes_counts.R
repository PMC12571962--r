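# Bayes factors for counts and correlations: Beta-binomial test against a
# point null, Gunel-Dickey independent-multinomial contingency test, and the
# stretched-beta Bayesian correlation test.

#' Bayesian binomial test
#'
#' Closed-form Bayes factor comparing a `Beta(a, b)` prior on the success
#' probability against the point null `p = p0`. Both marginal likelihoods are
#' of the same data, so the binomial coefficient cancels; with the default
#' uniform prior the factor reduces to `[1/(n+1)] / [C(n,k) p0^k (1-p0)^(n-k)]`
#' after restoring the coefficient on both sides.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param a,b Beta prior parameters (default uniform).
#' @return A `bf_result` with `method = "closed_form"`.
#' @examples
#' binomial_bf(16, 32) # balanced allocation of 32 subjects
#' @export
binomial_bf <- function(k, n, p0 = 0.5, a = 1, b = 1) {
  if (k < 0 || n < 0 || k > n) abort_argument("need 0 <= k <= n")
  assert_scalar_number(p0, "p0", lower = 1e-12, upper = 1 - 1e-12)
  log_m1 <- lbeta(k + a, n - k + b) - lbeta(a, b)
  log_m0 <- k * log(p0) + (n - k) * log(1 - p0)
  new_bf_result((log_m1 - log_m0) / log(10), "two_sided", NA_real_,
                "closed_form", k = k, n = n, p0 = p0)
}

#' Gunel-Dickey contingency-table Bayes factor
#'
#' Bayes factor for association in an `R x C` table of counts under
#' independent multinomial sampling (the group margins -- rows -- are fixed
#' by design). Each row's outcome distribution carries a symmetric
#' `Dirichlet(a)` prior under H1; under H0 all rows share one
#' `Dirichlet(a)` distribution. The factor is closed form in gamma
#' functions; multinomial coefficients are identical under both hypotheses
#' and cancel.
#'
#' @param tab Matrix (or table) of nonnegative integer counts; one row per
#'   group.
#' @param a Symmetric Dirichlet concentration (default 1).
#' @return A `bf_result` with `method = "closed_form"`.
#' @examples
#' contingency_bf(rbind(c(8, 8), c(8, 8))) # sex by group, perfectly balanced
#' @export
contingency_bf <- function(tab, a = 1) {
  tab <- as.matrix(tab)
  if (length(tab) == 0L || sum(tab) == 0) abort_argument("table is empty")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort_argument("counts must be nonnegative integers")
  }
  C <- ncol(tab)
  prior <- rep(a, C)
  log_m1 <- sum(apply(tab, 1L, function(y) lmbeta(y + prior) - lmbeta(prior)))
  log_m0 <- lmbeta(colSums(tab) + prior) - lmbeta(prior)
  new_bf_result((log_m1 - log_m0) / log(10), "two_sided", NA_real_,
                "closed_form", a = a, dim = dim(tab))
}

# Gauss hypergeometric 2F1 by power series; Pfaff-transformed for arguments
# near 1 so the series converges quickly. Scalar, log scale not needed here.
hyp2f1 <- function(a, b, c, x) {
  if (x >= 1) abort_argument("hyp2f1 requires x < 1")
  if (x > 0.6) {
    # linear transformation z -> 1 - z (valid for non-integer c - a - b)
    s <- c - a - b
    return(gamma(c) * gamma(s) / (gamma(c - a) * gamma(c - b)) *
             hyp2f1(a, b, 1 - s, 1 - x) +
           (1 - x)^s * gamma(c) * gamma(-s) / (gamma(a) * gamma(b)) *
             hyp2f1(c - a, c - b, 1 + s, 1 - x))
  }
  if (x < -1) {
    # Pfaff: pull large negative arguments inside the unit disc
    return((1 - x)^(-a) * hyp2f1(a, c - b, c, x / (x - 1)))
  }
  term <- 1; total <- 1
  for (k in 0:2000) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * x
    total <- total + term
    if (abs(term) < 1e-14 * abs(total)) break
  }
  total
}

# exact sampling density of the Pearson correlation r given rho (up to
# rho-free factors, which cancel in Bayes-factor ratios)
log_lik_rho <- function(rho, r, n) {
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2))
}

#' Bayesian correlation test
#'
#' Bayes factor for a nonzero Pearson correlation under a stretched-beta
#' prior on rho (uniform on (-1, 1) at the default width 1), integrating the
#' exact sampling density of the observed correlation coefficient over the
#' prior by adaptive quadrature.
#'
#' @param x,y Paired observations.
#' @param width Stretched-beta prior width `kappa`; the prior density is
#'   proportional to `(1 - rho^2)^(1/kappa - 1)`.
#' @return A `bf_result` carrying the sample correlation in `extra$r_obs`.
#' @export
bayes_correlation_bf <- function(x, y, width = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort_argument("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_argument("zero variance in x or y")
  }
  r_obs <- stats::cor(x, y)
  alpha <- 1 / width
  log_prior <- function(rho) (alpha - 1) * log1p(-rho^2) -
    lbeta(alpha, alpha) - (2 * alpha - 1) * log(2)
  f <- function(rho) {
    vapply(rho, function(p) {
      exp(log_prior(p) + log_lik_rho(p, r_obs, n) - log_lik_rho(0, r_obs, n))
    }, numeric(1))
  }
  m <- stats::integrate(f, -1, 1, rel.tol = 1e-8, stop.on.error = FALSE)$value
  new_bf_result(log10(m), "two_sided", width, "quadrature",
                r_obs = r_obs, n = n)
}
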