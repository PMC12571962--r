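# Parcel medians, covariate adjustment, the dual-threshold region rule,
# behavioural ANCOVAs and report rendering.

test_that("parcel medians are robust and match a sort-based oracle", {
  df <- tibble::tibble(subject_id = "s1", parcel_id = 1L, voxel = 1:3,
                       value = c(1, 2, 100))
  expect_equal(extract_parcel_medians(df)$estimate, 2)

  # single voxel per parcel: identity
  df1 <- tibble::tibble(subject_id = "s1", parcel_id = 1:4, voxel = 1L,
                        value = c(0.3, -1, 2, 5))
  expect_equal(extract_parcel_medians(df1)$estimate, c(0.3, -1, 2, 5))

  # random matrices against a sort-based median
  for (i in 1:5) {
    vals <- withr::with_seed(i, rnorm(30))
    df2 <- tibble::tibble(subject_id = "s1", parcel_id = rep(1:5, each = 6),
                          voxel = rep(1:6, 5), value = vals)
    med <- extract_parcel_medians(df2)
    oracle <- vapply(1:5, function(p) {
      v <- sort(vals[rep(1:5, each = 6) == p])
      (v[3] + v[4]) / 2
    }, numeric(1))
    expect_equal(med$estimate, oracle, tolerance = 1e-12)
  }

  # parcels with no voxels are completed as NA with a warning
  atlas <- default_atlas(6, seed_parcels = c(L = 5L, R = 6L))
  expect_warning(out <- extract_parcel_medians(df1, atlas = atlas),
                 "no voxels")
  expect_equal(sum(is.na(out$estimate)), 2L)
})

test_that("covariate adjustment removes confounds but preserves group signal", {
  n <- 24
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("PATIENT", "HC"), each = n / 2),
    sex = rep(c("F", "M"), n / 2),
    age = withr::with_seed(1, round(runif(n, 20, 50))),
    bdi2 = withr::with_seed(2, round(runif(n, 0, 10))))

  # estimates orthogonal to the covariates: adjustment is a no-op
  X <- stats::model.matrix(~ sex + age + bdi2, data = subjects)
  raw <- withr::with_seed(3, rnorm(n))
  ortho <- raw - X %*% qr.coef(qr(X), raw)
  est <- structure(tibble::tibble(subject_id = subjects$subject_id,
                                  parcel_id = 1L,
                                  estimate = as.vector(ortho) + 2),
                   endpoint = "t", adjusted = FALSE,
                   class = c("parcel_estimates", class(tibble::tibble())))
  adj <- adjust_covariates(est, subjects)
  expect_equal(adj$estimate, est$estimate, tolerance = 1e-9)

  # planted pure-age effect: residual correlation with age ~ 0
  est2 <- est
  est2$estimate <- 0.1 * subjects$age + withr::with_seed(4, rnorm(n, 0, 0.01))
  adj2 <- adjust_covariates(est2, subjects)
  expect_lt(abs(cor(adj2$estimate, subjects$age)), 1e-9)

  # collinear covariates dropped with a warning
  subjects$age2 <- subjects$age
  expect_warning(adjust_covariates(est, subjects,
                                   covariates = c("age", "age2")),
                 "collinear")
})

test_that("adjusting out an age confound sharpens the group Bayes factor", {
  n <- 16
  better <- vapply(1:100, function(i) {
    withr::with_seed(5000 + i, {
      subjects <- tibble::tibble(
        subject_id = sprintf("s%02d", 1:(2 * n)),
        group = rep(c("PATIENT", "HC"), each = n),
        sex = sample(rep(c("F", "M"), n)),
        age = rnorm(2 * n, 31, 8),
        bdi2 = pmax(0, rnorm(2 * n, 4, 3)))
      y <- 0.4 * (subjects$group == "PATIENT") + 0.08 * subjects$age +
        rnorm(2 * n, 0, 0.2)
    })
    est <- structure(tibble::tibble(subject_id = subjects$subject_id,
                                    parcel_id = 1L, estimate = y),
                     endpoint = "t", adjusted = FALSE,
                     class = c("parcel_estimates", class(tibble::tibble())))
    raw_bf <- test_regions(est, subjects)$log10_bf_diff
    adj_bf <- test_regions(adjust_covariates(est, subjects),
                           subjects)$log10_bf_diff
    adj_bf - raw_bf
  }, numeric(1))
  expect_gt(median(better), 0)
})

test_that("region decisions implement the dual-threshold rule", {
  n <- 16
  subjects <- tibble::tibble(subject_id = sprintf("s%02d", 1:(2 * n)),
                             group = rep(c("HC", "PATIENT"), each = n))
  est <- withr::with_seed(77, {
    vals <- c(rnorm(n, -0.3, 0.15),  # HC decrease
              rnorm(n, 0.3, 0.15))   # patient increase -> strong difference
    null_vals <- rnorm(2 * n, 0, 0.2)
    tibble::tibble(subject_id = rep(subjects$subject_id, 2),
                   parcel_id = rep(1:2, each = 2 * n),
                   estimate = c(vals, null_vals))
  })
  class(est) <- c("parcel_estimates", class(est))
  dec <- test_regions(est, subjects)
  expect_equal(dec$verdict[dec$parcel_id == 1], "difference")
  expect_true(dec$reported[dec$parcel_id == 1])

  # clause (2): raising the main-effect threshold turns reporting off
  dec_hi <- test_regions(est, subjects, main_threshold = Inf)
  expect_equal(dec_hi$verdict[dec_hi$parcel_id == 1], "difference")
  expect_false(dec_hi$reported[dec_hi$parcel_id == 1])

  # verdicts partition every parcel exactly once
  expect_true(all(dec$verdict %in% c("difference", "similarity", "undecided")))
  expect_equal(nrow(dec), 2L)

  # degenerate zero-variance parcel -> undecided and flagged
  est0 <- est
  est0$estimate[est0$parcel_id == 2] <- 1
  dec0 <- test_regions(est0, subjects)
  expect_equal(dec0$verdict[dec0$parcel_id == 2], "undecided")
  expect_true(dec0$degenerate[dec0$parcel_id == 2])

  # reported rows always satisfy both clauses (audit re-check)
  aud <- dec[dec$reported, ]
  if (nrow(aud)) {
    expect_true(all(aud$log10_bf_diff > 1))
    expect_true(all(pmax(aud$log10_bf_1_greater, aud$log10_bf_1_less,
                         aud$log10_bf_2_greater, aud$log10_bf_2_less) > 0.5))
  }
})

test_that("groups with matched means earn a similarity verdict", {
  # the two-sample JZS BF is bounded below by its value at t = 0, which only
  # drops past the -0.5 similarity cut once each group exceeds ~20 subjects;
  # use 24 per group so the similarity branch of the rule is reachable
  n <- 24
  subjects <- tibble::tibble(subject_id = sprintf("s%02d", 1:(2 * n)),
                             group = rep(c("HC", "PATIENT"), each = n))
  vals <- withr::with_seed(88, rnorm(n, 0, 0.25))
  est <- tibble::tibble(subject_id = subjects$subject_id, parcel_id = 1L,
                        estimate = c(vals, vals))
  class(est) <- c("parcel_estimates", class(est))
  dec <- test_regions(est, subjects)
  expect_equal(dec$verdict, "similarity")
  expect_lt(dec$log10_bf_diff, -0.5)
})

test_that("behavioural analysis gates post-hoc tests on the interaction evidence", {
  cfg_null <- sim_config(n_per_group = 16L,
                         rating_model = list(patient_valence_shrink = 0,
                                             patient_arousal_shift = 0),
                         seed = 31L)
  coh <- simulate_cohort(cfg_null, simulate_ts = FALSE)
  res <- behavioral_analysis(behavioral_table(coh, "valence"),
                             mcmc_passes = 1500, seed = 1)
  expect_equal(nrow(res$posthoc), 0L)

  cfg_eff <- sim_config(n_per_group = 16L, seed = 32L)
  coh2 <- simulate_cohort(cfg_eff, simulate_ts = FALSE)
  res2 <- behavioral_analysis(behavioral_table(coh2, "valence"),
                              mcmc_passes = 1500, seed = 2)
  ix <- res2$inclusion$log10_bf_incl[res2$inclusion$predictor == "interaction"]
  expect_gt(ix, 0.5)
  expect_gt(nrow(res2$posthoc), 0L)
  expect_true(all(c("level", "direction", "log10_bf") %in% names(res2$posthoc)))

  # scalar outcome: no within factor, only the group effect is assessed
  res3 <- behavioral_analysis(behavioral_table(coh, "recognition_performance"),
                              mcmc_passes = 1000, seed = 3)
  expect_equal(res3$inclusion$predictor, "between")
})

test_that("reports audit the selection rule and survive empty inputs", {
  n <- 16
  subjects <- tibble::tibble(subject_id = sprintf("s%02d", 1:(2 * n)),
                             group = rep(c("HC", "PATIENT"), each = n))
  est <- withr::with_seed(99, tibble::tibble(
    subject_id = rep(subjects$subject_id, 3),
    parcel_id = rep(1:3, each = 2 * n),
    estimate = c(rnorm(n, -0.3, 0.12), rnorm(n, 0.3, 0.12),
                 rnorm(2 * n, 0, 0.2), rnorm(2 * n, 0, 1))))
  class(est) <- c("parcel_estimates", class(est))
  dec <- test_regions(est, subjects)
  dir <- withr::local_tempdir()
  paths <- render_report(dec, atlas = default_atlas(3, c(L = 2L, R = 3L)),
                         endpoint = "dBR_N", dir = dir)
  expect_true(all(file.exists(paths)))
  tab <- readr::read_tsv(paths[["tsv"]], show_col_types = FALSE)
  expect_equal(nrow(tab), 3L)
  # regions ordered by descending absolute evidence
  expect_true(!is.unsorted(rev(abs(tab$log10_bf_diff))))
  # every reported row satisfies the rule
  rep_rows <- tab[tab$reported, ]
  if (nrow(rep_rows)) {
    expect_true(all(rep_rows$log10_bf_diff > 1))
    expect_true(all(pmax(rep_rows$log10_bf_1_greater, rep_rows$log10_bf_1_less,
                         rep_rows$log10_bf_2_greater,
                         rep_rows$log10_bf_2_less) > 0.5))
  }

  empty <- dec[0, ]
  paths0 <- render_report(empty, endpoint = "empty", dir = dir)
  tab0 <- readr::read_tsv(paths0[["tsv"]], show_col_types = FALSE)
  expect_equal(nrow(tab0), 0L)
  expect_gt(length(readLines(paths0[["txt"]])), 0L)
})

test_that("tidiers and plots return the documented shapes", {
  h <- canonical_hrf(0.5)
  expect_s3_class(autoplot(h), "ggplot")
  cfg <- tiny_config()
  ev <- tiny_events(cfg)
  expect_s3_class(autoplot(ev), "ggplot")
  d <- build_model1_design(ev, tiny_motion(cfg$n_volumes), cfg$n_volumes, 2)
  td <- tidy(d)
  expect_equal(nrow(td), cfg$n_volumes * ncol(d$matrix))
  ts <- withr::with_seed(1, simulate_subject(cfg, "HC", ev))
  fit <- fit_glm(dct_highpass(d), ts)
  expect_equal(nrow(glance(fit)), 1L)
  expect_equal(nrow(tidy(fit)), ncol(ts$data) * ncol(d$matrix))
  b <- jzs_one_sample_bf(rnorm(5))
  expect_s3_class(tidy(b), "tbl_df")
})
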