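# Bayes factors: printed-value anchors, closed forms, identities and
# Monte-Carlo oracles.

test_that("demographic-table Bayes factors match the published values", {
  expect_equal(round(binomial_bf(16, 32)$log10_bf10, 3), -0.664)
  expect_lt(abs(contingency_bf(rbind(c(8, 8), c(8, 8)))$log10_bf10 - (-0.383)),
            0.005)
  rows <- list(
    list(m1 = 32.63, sd1 = 9.13, m2 = 28.44, sd2 = 7.95, bf = -0.159),  # age
    list(m1 = 29.93, sd1 = 0.26, m2 = 29.69, sd2 = 0.60, bf = -0.121),  # MMSE
    list(m1 = 1.75, sd1 = 1.65, m2 = 1.63, sd2 = 1.78, bf = -0.466),    # HADS-D
    list(m1 = 13.31, sd1 = 12.97, m2 = 11.93, sd2 = 9.48, bf = -0.450)) # MFIS
  for (row in rows) {
    got <- jzs_two_sample_bf(stats = list(m1 = row$m1, sd1 = row$sd1, n1 = 16,
                                          m2 = row$m2, sd2 = row$sd2, n2 = 16))
    expect_lt(abs(got$log10_bf10 - row$bf), 0.05)
  }
})

test_that("binomial Bayes factor has its closed-form limits", {
  expect_equal(binomial_bf(0, 0)$log10_bf10, 0)
  # direct Beta integral: k=2, n=2 -> (1/3) / (1/4)
  expect_equal(binomial_bf(2, 2)$log10_bf10, log10(4 / 3), tolerance = 1e-12)
  expect_error(binomial_bf(3, 2), class = "bayesbold_argument_error")
})

test_that("contingency Bayes factor grows with association and matches Monte Carlo", {
  bfs <- vapply(c(2, 4, 8, 16), function(N) {
    contingency_bf(rbind(c(N, 0), c(0, N)))$log10_bf10
  }, numeric(1))
  expect_true(all(bfs > 0))
  expect_true(all(diff(bfs) > 0))
  expect_error(contingency_bf(matrix(0, 2, 2)),
               class = "bayesbold_argument_error")

  # Monte-Carlo marginal-likelihood oracle on a small table
  tab <- rbind(c(3, 5), c(6, 2))
  got <- contingency_bf(tab)$log10_bf10
  draws <- 1e6
  withr::with_seed(42, {
    th1 <- matrix(rgamma(2 * draws, 1), ncol = 2)  # Dirichlet(1,1) rows
    th1 <- th1 / rowSums(th1)
    lik_row <- function(y) th1[, 1]^y[1] * th1[, 2]^y[2]
    m1 <- mean(lik_row(tab[1, ])) * mean(lik_row(tab[2, ]))
    m0 <- mean(lik_row(colSums(tab)))
  })
  mc <- log10(m1 / m0)
  # generous: MC error of the product of means, on the log scale
  expect_lt(abs(got - mc), 0.02)
})

test_that("JZS factors are symmetric at the null and respect prior splitting", {
  # symmetric data about zero: both one-sided factors agree
  x <- c(-2, -1, 1, 2, -0.5, 0.5)
  bg <- jzs_one_sample_bf(x, direction = "greater")$log10_bf10
  bl <- jzs_one_sample_bf(x, direction = "less")$log10_bf10
  b2 <- jzs_one_sample_bf(x, direction = "two_sided")$log10_bf10
  expect_equal(bg, bl, tolerance = 1e-8)
  expect_lt(b2, 0)
  # two-sample with t = 0
  y1 <- c(1, 2, 3, 4); y2 <- c(4, 1, 3, 2)
  expect_equal(jzs_two_sample_bf(y1, y2, direction = "greater")$log10_bf10,
               jzs_two_sample_bf(y1, y2, direction = "less")$log10_bf10,
               tolerance = 1e-8)

  # prior-splitting identity over random datasets
  for (i in 1:50) {
    x <- withr::with_seed(1000 + i, rnorm(8, mean = runif(1, -1, 1)))
    b2 <- jzs_one_sample_bf(x)$log10_bf10
    bg <- jzs_one_sample_bf(x, direction = "greater")$log10_bf10
    bl <- jzs_one_sample_bf(x, direction = "less")$log10_bf10
    expect_equal(log10((10^bg + 10^bl) / 2), b2, tolerance = 1e-6)
  }
})

test_that("JZS factors are exactly invariant to affine rescaling of the data", {
  x <- withr::with_seed(7, rnorm(12, 0.5))
  y <- withr::with_seed(8, rnorm(10, 0.1))
  b <- jzs_two_sample_bf(x, y)$log10_bf10
  expect_identical(jzs_two_sample_bf(3.2 * x + 7, 3.2 * y + 7)$log10_bf10, b)
})

test_that("one-sided evidence grows without bound as the effect sharpens", {
  bfs <- vapply(c(1, 0.3, 0.1, 0.03), function(s) {
    jzs_one_sample_bf(stats = list(mean = 1, sd = s, n = 10),
                      direction = "greater")$log10_bf10
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[length(bfs)], 3)
})

test_that("quadrature matches a million-draw Monte-Carlo prior average", {
  for (i in 1:3) {
    x <- withr::with_seed(60 + i, rnorm(8, 0.5))
    y <- withr::with_seed(70 + i, rnorm(8))
    b <- jzs_two_sample_bf(x, y)
    tstat <- b$extra$t; df <- b$extra$df; N <- 4
    withr::with_seed(80 + i, {
      del <- rcauchy(1e6, 0, sqrt(2) / 2)
      lik <- suppressWarnings(dt(tstat, df, ncp = del * sqrt(N)))
    })
    mc <- mean(lik) / dt(tstat, df)
    se <- sd(lik) / sqrt(1e6) / dt(tstat, df)
    expect_lt(abs(10^b$log10_bf10 - mc), 3 * se)
  }
})

test_that("degenerate t-test inputs raise argument errors", {
  expect_error(jzs_one_sample_bf(1), class = "bayesbold_argument_error")
  expect_error(jzs_one_sample_bf(c(2, 2, 2)), class = "bayesbold_argument_error")
  expect_error(jzs_two_sample_bf(c(1, 1), c(2, 2)),
               class = "bayesbold_argument_error")
})

test_that("correlation Bayes factors favour the null at r = 0 and grow in |r|", {
  n <- 20
  make_xy <- function(r_target) {
    # construct the exact sample correlation by Gram-Schmidt
    x <- scale(withr::with_seed(1, rnorm(n)))[, 1]
    e <- withr::with_seed(2, rnorm(n))
    e <- e - sum(e * x) / sum(x * x) * x
    e <- scale(e)[, 1]
    list(x = x, y = r_target * x + sqrt(1 - r_target^2) * e)
  }
  b0 <- bayes_correlation_bf(make_xy(0)$x, make_xy(0)$y)$log10_bf10
  expect_lt(b0, 0)
  bfs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(r) {
    d <- make_xy(r)
    bayes_correlation_bf(d$x, d$y)$log10_bf10
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_error(bayes_correlation_bf(1:5, rep(2, 5)),
               class = "bayesbold_argument_error")
})

test_that("correlation quadrature matches the Monte-Carlo prior average", {
  x <- withr::with_seed(11, rnorm(20))
  y <- 0.5 * x + withr::with_seed(12, rnorm(20))
  got <- bayes_correlation_bf(x, y)$log10_bf10
  r_obs <- cor(x, y)
  withr::with_seed(13, {
    rho <- runif(2e5, -1, 1)
    w <- vapply(rho, function(p) {
      exp(bayesbold:::log_lik_rho(p, r_obs, 20) -
            bayesbold:::log_lik_rho(0, r_obs, 20))
    }, numeric(1))
  })
  expect_lt(abs(got - log10(mean(w))), 3 * sd(w) / mean(w) / sqrt(2e5) / log(10))
})

test_that("evidence grades follow the reporting thresholds", {
  expect_equal(grade_evidence(1.70), "strong_H1")
  expect_equal(grade_evidence(-0.512), "moderate_H0")
  expect_equal(grade_evidence(0), "anecdotal")
  expect_equal(grade_evidence(c(0.66, -1.2, 0.4)),
               c("moderate_H1", "strong_H0", "anecdotal"))
})

test_that("inclusion Bayes factors respect the model-space bookkeeping", {
  cfg <- sim_config(n_per_group = 8L)
  coh <- simulate_cohort(cfg, simulate_ts = FALSE)
  b <- behavioral_table(coh, "valence")
  f <- rmancova_inclusion_bf(b, "response", "subject_id", within = "level",
                             between = "group",
                             covariates = c("age", "sex", "iaps_set", "bdi2"),
                             mcmc_passes = 1500, seed = 5)
  expect_equal(sum(f$models$post_prob), 1, tolerance = 1e-9)
  expect_equal(nrow(f$models), 5L)
  expect_setequal(f$inclusion$predictor, c("within", "between", "interaction"))
  # reproducible under the seed
  f2 <- rmancova_inclusion_bf(b, "response", "subject_id", within = "level",
                              between = "group",
                              covariates = c("age", "sex", "iaps_set", "bdi2"),
                              mcmc_passes = 1500, seed = 5)
  expect_identical(f$inclusion$log10_bf_incl, f2$inclusion$log10_bf_incl)
  # matched-models variant runs and reports the same predictors
  fm <- rmancova_inclusion_bf(b, "response", "subject_id", within = "level",
                              between = "group", mcmc_passes = 500, seed = 5,
                              matched_models = TRUE)
  expect_setequal(fm$inclusion$predictor, c("within", "between", "interaction"))

  bad <- b[-1, ]
  expect_error(
    rmancova_inclusion_bf(bad, "response", "subject_id", within = "level",
                          between = "group"),
    class = "bayesbold_validation_error")
})

test_that("tiny-dataset marginal likelihoods match a brute-force quadrature oracle", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                  level = rep(c("L1", "L2"), 2),
                  group = rep(c("G1", "G2"), each = 2),
                  response = c(1.0, 2.0, 1.5, 0.5))
  f <- rmancova_inclusion_bf(d, "response", "subject_id", within = "level",
                             between = "group", mcmc_passes = 20000, seed = 3)

  Q <- function(a) {
    H <- stats::contr.helmert(a)
    sweep(H, 2, sqrt(colSums(H^2)), "/")
  }
  y <- d$response; yc <- y - mean(y); n <- 4
  Xs <- Q(2)[as.integer(factor(d$subject_id)), , drop = FALSE]
  Xw <- Q(2)[as.integer(factor(d$level)), , drop = FALSE]
  Xb <- Q(2)[as.integer(factor(d$group)), , drop = FALSE]
  Xi <- Xw * Xb[, 1]
  logp <- function(X, gvec) {
    Xc <- sweep(X, 2, colMeans(X)); sg <- sqrt(gvec)
    S <- crossprod(Xc) * tcrossprod(sg); diag(S) <- diag(S) + 1
    R <- chol(S); u <- sg * as.vector(crossprod(Xc, yc))
    v <- backsolve(R, u, transpose = TRUE)
    -sum(log(diag(R))) - (n - 1) / 2 * log(sum(yc^2) - sum(v^2))
  }
  qg <- function(v, r) 1 / qgamma(1 - v, 0.5, rate = r^2 / 2)
  mid <- function(m) (seq_len(m) - 0.5) / m
  rf <- sqrt(2) / 2
  # null: subject only (1-d quadrature over its g)
  or_null <- log(mean(exp(vapply(qg(mid(2000), 1),
                                 function(g) logp(Xs, g), numeric(1)))))
  # within: subject + category (2-d)
  gs <- qg(mid(120), 1); gw <- qg(mid(120), rf)
  or_w <- log(mean(exp(outer(gs, gw, Vectorize(
    function(a, b) logp(cbind(Xs, Xw), c(a, b)))))))
  # full model: subject + within + between + interaction (4-d)
  g10 <- qg(mid(10), 1); f10 <- qg(mid(10), rf)
  grid <- expand.grid(gs = g10, gw = f10, gb = f10, gi = f10)
  or_full <- log(mean(exp(apply(grid, 1, function(gv) {
    logp(cbind(Xs, Xw, Xb, Xi), gv)
  }))))

  m <- f$models
  expect_lt(abs(m$log_marginal[m$model == "null"] - or_null),
            max(3 * m$mc_se[m$model == "null"], 0.02))
  expect_lt(abs(m$log_marginal[m$model == "within"] - or_w),
            max(3 * m$mc_se[m$model == "within"], 0.02))
  expect_lt(abs(m$log_marginal[m$model == "within+between+interaction"] - or_full),
            max(3 * m$mc_se[m$model == "within+between+interaction"], 0.05))
})
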