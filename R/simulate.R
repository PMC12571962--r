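# Synthetic cohorts with the statistical structure the analysis assumes:
# a two-group picture-rating paradigm with planted group effects in category
# amplitude, rating slope and seed connectivity.

#' Simulation configuration
#'
#' Collects every tunable of the cohort generator. The defaults reproduce
#' the study design being emulated: two groups of 16 subjects, 54 trials (18
#' per valence category crossed with 27 low/27 high arousal), 6 s picture
#' epochs followed by up to 8 s of rating, 10-14 s onset asynchrony, 470
#' volumes at TR = 2 s, 246 parcels of 10 voxels.
#'
#' @param n_per_group Subjects per group (PATIENT and HC).
#' @param n_parcels,voxels_per_parcel Parcellation geometry.
#' @param tr_s,n_volumes Acquisition timing.
#' @param n_trials Number of trials; must divide evenly into the 3 x 2
#'   category-by-arousal cross.
#' @param soa_range_s Uniform range of successive picture-onset asynchronies.
#' @param picture_duration_s,rating_max_s Epoch durations (ratings are
#'   response-terminated, at most `rating_max_s`).
#' @param bins_per_tr Microtime bins per TR used when convolving.
#' @param baseline Mean signal level added to every voxel.
#' @param amplitudes List: `category_base` (response of every parcel to any
#'   picture), `press` (response per button press).
#' @param noise List: `white_sd` (marginal SD of the AR(1) noise),
#'   `ar1` (lag-1 coefficient), `drift_amplitude` and `drift_period_s`
#'   (sinusoidal scanner drift; the default period matches the high-pass
#'   cutoff so the filter removes it).
#' @param rating_model List controlling the latent-Gaussian ordinal rating
#'   model: `valence_means` (per category), `arousal_means` (per arousal
#'   class), `subject_sd` (between-subject offset), `noise_sd` (trial
#'   noise), `patient_valence_shrink` (rating points by which patient NEG and
#'   POS means move toward the neutral midpoint 5), `patient_arousal_shift`
#'   (added to patient arousal means).
#' @param connectivity List: `seed_fluct_sd` (SD of the smooth intrinsic
#'   neural fluctuation of the seed parcels), `baseline_gain` (task-
#'   independent coupling of PPI target parcels to the seed),
#'   `fluct_smooth_s` (Gaussian smoothing width of the fluctuation).
#' @param covariate_model List of means/SDs for age, BDI-2 and recognition
#'   outcomes.
#' @param effects List of [planted_effect()] objects (default none).
#' @param effect_subject_sd Between-subject SD of every planted magnitude.
#' @param voxel_gain_sd Multiplicative spread of task amplitude across a
#'   parcel's voxels.
#' @param seed Root seed; cohorts are bit-identical under a fixed seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 16L, n_parcels = 246L,
                       voxels_per_parcel = 10L, tr_s = 2, n_volumes = 470L,
                       n_trials = 54L, soa_range_s = c(10, 14),
                       picture_duration_s = 6, rating_max_s = 8,
                       bins_per_tr = 16L, baseline = 100,
                       amplitudes = list(),
                       noise = list(), rating_model = list(),
                       connectivity = list(), covariate_model = list(),
                       effects = list(), effect_subject_sd = 0.05,
                       voxel_gain_sd = 0.1, seed = 1L) {
  amplitudes <- utils::modifyList(
    list(category_base = 0.8, press = 0.3), amplitudes)
  noise <- utils::modifyList(
    list(white_sd = 1, ar1 = 0.3, drift_amplitude = 1, drift_period_s = 128),
    noise)
  rating_model <- utils::modifyList(
    list(valence_means = c(NEG = 2.8, NEU = 5, POS = 7.2),
         arousal_means = c(LOW = 3.2, HIGH = 6.2),
         subject_sd = 0.5, noise_sd = 1,
         patient_valence_shrink = 1.5, patient_arousal_shift = -0.7),
    rating_model)
  connectivity <- utils::modifyList(
    list(seed_fluct_sd = 1, baseline_gain = 0.3, fluct_smooth_s = 4),
    connectivity)
  covariate_model <- utils::modifyList(
    list(age_mean = 30.5, age_sd = 8.5, bdi_mean = 3.8, bdi_sd = 4,
         recognition_mean = 85, recognition_sd = 8,
         rt_mean = 900, rt_sd = 150),
    covariate_model)
  if (noise$white_sd < 0 || noise$drift_amplitude < 0) {
    abort_config("noise standard deviations must be nonnegative")
  }
  if (abs(noise$ar1) >= 1) abort_config("`ar1` must lie in (-1, 1)")
  if (n_trials %% 6L != 0L) {
    abort_config("`n_trials` must divide into the 3 x 2 category/arousal cross")
  }
  if (rating_model$subject_sd < 0 || rating_model$noise_sd < 0) {
    abort_config("rating-model standard deviations must be nonnegative")
  }
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_parcels = as.integer(n_parcels),
              voxels_per_parcel = as.integer(voxels_per_parcel),
              tr_s = tr_s, n_volumes = as.integer(n_volumes),
              n_trials = as.integer(n_trials), soa_range_s = soa_range_s,
              picture_duration_s = picture_duration_s,
              rating_max_s = rating_max_s,
              bins_per_tr = as.integer(bins_per_tr), baseline = baseline,
              amplitudes = amplitudes, noise = noise,
              rating_model = rating_model, connectivity = connectivity,
              covariate_model = covariate_model, effects = effects,
              effect_subject_sd = effect_subject_sd,
              voxel_gain_sd = voxel_gain_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Planted ground-truth effect
#'
#' Describes one effect injected into simulated cohorts: a category-specific
#' amplitude increase, a valence-rating slope, or a gain on the modulation of
#' seed connectivity by negative picture content.
#'
#' @param kind One of `"category_amplitude"`, `"valence_slope"`, `"ppi_gain"`.
#' @param parcel_ids Target parcels.
#' @param group `"PATIENT"`, `"HC"` or `"BOTH"`.
#' @param magnitude Signal units for amplitudes, signal units per rating point
#'   for slopes, gain units for connectivity modulation.
#' @param seed_id Seed parcel (required for `"ppi_gain"`).
#' @param category Category whose amplitude is raised (for
#'   `"category_amplitude"`).
#' @return A list of class `planted_effect`.
#' @export
planted_effect <- function(kind, parcel_ids, group = "PATIENT", magnitude,
                           seed_id = NULL, category = "NEG") {
  kind <- match.arg(kind, c("category_amplitude", "valence_slope", "ppi_gain"))
  group <- match.arg(group, c("PATIENT", "HC", "BOTH"))
  if (kind == "ppi_gain" && is.null(seed_id)) {
    abort_config("`ppi_gain` effects must name a seed parcel")
  }
  structure(list(kind = kind, parcel_ids = as.integer(parcel_ids),
                 group = group, magnitude = magnitude,
                 seed_id = if (is.null(seed_id)) NA_integer_ else as.integer(seed_id),
                 category = category),
            class = "planted_effect")
}

#' Default planted-effect set
#'
#' A qualitative emulation of the group-difference pattern the analysis is
#' designed to detect: patients show an increased (and controls a decreased)
#' response to negative pictures in two frontal parcels, opposite valence
#' slopes in the amygdala parcels, and a patient-only increase in the
#' negative-picture modulation of right-amygdala connectivity with three
#' distant parcels.
#'
#' @param atlas Atlas lookup (see [default_atlas()]).
#' @return A list of [planted_effect()]s.
#' @export
default_effects <- function(atlas = default_atlas()) {
  seeds <- atlas$parcel_id[atlas$is_seed]
  right_seed <- seeds[length(seeds)]
  list(
    planted_effect("category_amplitude", c(5L, 15L), "PATIENT", 0.4),
    planted_effect("category_amplitude", c(5L, 15L), "HC", -0.4),
    planted_effect("valence_slope", seeds, "PATIENT", -0.12),
    planted_effect("valence_slope", seeds, "HC", 0.12),
    planted_effect("ppi_gain", c(100L, 120L, 140L), "PATIENT", 0.8,
                   seed_id = right_seed)
  )
}

#' Simulate one subject's trial events and ratings
#'
#' Draws a randomised trial order for the category-by-arousal cross, onset
#' asynchronies uniform on the configured range, response-terminated rating
#' epochs and button presses, and per-trial SAM ratings from a latent-
#' Gaussian ordinal model: latent value = category (or arousal-class) mean +
#' subject offset + trial noise, rounded and clamped to the 9-point scale.
#' For patients the NEG and POS valence means are shrunk toward the neutral
#' midpoint and arousal means shifted, emulating flattened emotional
#' experience. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param group `"HC"` or `"PATIENT"`.
#' @return An [event_table()].
#' @export
simulate_events <- function(config, group = "HC") {
  stopifnot(inherits(config, "sim_config"))
  rm <- config$rating_model
  per_cell <- config$n_trials / 6L
  grid <- expand.grid(category = c("NEG", "NEU", "POS"),
                      arousal_class = c("LOW", "HIGH"),
                      stringsAsFactors = FALSE)
  trials <- grid[rep(seq_len(nrow(grid)), each = per_cell), ]
  trials <- trials[sample.int(nrow(trials)), ]
  n <- nrow(trials)

  soa <- stats::runif(n - 1, config$soa_range_s[1], config$soa_range_s[2])
  onsets <- 10 + c(0, cumsum(soa))
  run_s <- config$n_volumes * config$tr_s
  if (max(onsets) + config$picture_duration_s + config$rating_max_s > run_s) {
    abort_config("trial timing exceeds the run duration; reduce trials or SOA")
  }

  vmeans <- rm$valence_means
  ameans <- rm$arousal_means
  if (group == "PATIENT") {
    shrink <- rm$patient_valence_shrink
    vmeans <- vmeans + pmin(abs(5 - vmeans), shrink) * sign(5 - vmeans)
    ameans <- ameans + rm$patient_arousal_shift
  }
  subj_off_v <- stats::rnorm(1, 0, rm$subject_sd)
  subj_off_a <- stats::rnorm(1, 0, rm$subject_sd)
  clamp <- function(z) pmin(9L, pmax(1L, as.integer(round(z))))
  valence <- clamp(vmeans[trials$category] + subj_off_v +
                     stats::rnorm(n, 0, rm$noise_sd))
  arousal <- clamp(ameans[trials$arousal_class] + subj_off_a +
                     stats::rnorm(n, 0, rm$noise_sd))

  rating_onset <- onsets + config$picture_duration_s
  rating_dur <- stats::runif(n, 2, config$rating_max_s)
  presses <- lapply(seq_len(n), function(i) {
    rating_onset[i] + sort(stats::runif(2, 0.3, rating_dur[i]))
  })
  event_table(tibble::tibble(
    trial_id = seq_len(n), onset_s = onsets,
    picture_duration_s = config$picture_duration_s,
    category = trials$category, arousal_class = trials$arousal_class,
    valence_rating = valence, arousal_rating = arousal,
    rating_onset_s = rating_onset, rating_duration_s = rating_dur,
    button_press_times_s = presses
  ))
}

# smooth intrinsic neural fluctuation at microtime resolution
seed_fluctuation <- function(n_micro, dt, sd, smooth_s) {
  z <- stats::rnorm(n_micro)
  w <- stats::dnorm(seq(-3 * smooth_s, 3 * smooth_s, by = dt), sd = smooth_s)
  s <- stats::filter(c(rev(z[seq_along(w)]), z, rev(z)[seq_along(w)]),
                     w / sum(w), sides = 2)
  s <- s[(length(w) + 1):(length(w) + n_micro)]
  s <- s - mean(s)
  if (stats::sd(s) > 0) s <- s / stats::sd(s) * sd
  as.numeric(s)
}

effect_applies <- function(e, group) e$group == "BOTH" || e$group == group

#' Simulate one subject's parcel time series
#'
#' Builds each voxel's signal as the sum of HRF-convolved neural regressors
#' (category boxcars, button-press sticks, rating-modulated epochs and
#' psychophysiological interactions for the planted effects), a sinusoidal
#' low-frequency drift, and AR(1) Gaussian noise. Connectivity effects are
#' injected at the neural (pre-convolution) level: target parcels receive
#' `gain x (seed neural signal x centred NEG-vs-NEU psychological vector)`
#' before convolution, which is exactly the structure the PPI estimator
#' assumes. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param group Subject's group.
#' @param events The subject's [event_table()].
#' @param atlas Atlas lookup used to locate seed parcels.
#' @return A [parcel_ts()].
#' @export
simulate_subject <- function(config, group, events, atlas = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(atlas)) atlas <- default_atlas(config$n_parcels)
  bins <- config$bins_per_tr
  n_vol <- config$n_volumes
  tr <- config$tr_s
  dt <- tr / bins
  n_micro <- micro_length(n_vol, bins)
  hrf <- canonical_hrf(dt)

  conv <- function(neural) convolve_regressor(neural, hrf, n_vol, bins)
  cat_col <- function(cc) {
    ev <- events[events$category == cc, ]
    conv(neural_boxcar(ev$onset_s, ev$picture_duration_s, n_micro, dt))
  }
  C_cat <- sapply(c("NEG", "NEU", "POS"), cat_col)
  press <- conv(neural_sticks(unlist(events$button_press_times_s), n_micro, dt))
  val_amp <- events$valence_rating - mean(events$valence_rating)
  M_val <- conv(neural_boxcar(events$onset_s, events$picture_duration_s,
                              n_micro, dt, amplitudes = val_amp))

  base <- config$baseline +
    config$amplitudes$category_base * rowSums(C_cat) +
    config$amplitudes$press * press

  # seed neural signals (per seed parcel): intrinsic fluctuation + task drive
  effects <- config$effects
  ppi_effects <- Filter(function(e) e$kind == "ppi_gain", effects)
  seed_ids <- unique(c(atlas$parcel_id[atlas$is_seed],
                       vapply(ppi_effects, `[[`, integer(1), "seed_id")))
  seed_ids <- seed_ids[!is.na(seed_ids)]
  task_micro <- neural_boxcar(events$onset_s, events$picture_duration_s,
                              n_micro, dt) * config$amplitudes$category_base
  seed_neural <- lapply(stats::setNames(seed_ids, seed_ids), function(sid) {
    task_micro + seed_fluctuation(n_micro, dt, config$connectivity$seed_fluct_sd,
                                  config$connectivity$fluct_smooth_s)
  })
  seed_bold <- lapply(seed_neural, conv)
  p_negneu <- psych_vector(events, "NEG", "NEU", n_micro, dt)
  ppi_bold <- lapply(seed_neural, function(s) conv(s * p_negneu))

  # per-parcel mean task signal
  mean_signal <- matrix(rep(base, config$n_parcels), ncol = config$n_parcels)
  for (sid in seed_ids) {
    mean_signal[, sid] <- mean_signal[, sid] + seed_bold[[as.character(sid)]] -
      config$amplitudes$category_base * rowSums(C_cat)
  }
  for (e in effects) {
    if (!effect_applies(e, group)) next
    if (any(e$parcel_ids > config$n_parcels)) {
      abort_config("planted effect references a parcel outside the atlas")
    }
    for (p in e$parcel_ids) {
      mag <- e$magnitude + stats::rnorm(1, 0, config$effect_subject_sd)
      add <- switch(e$kind,
        category_amplitude = mag * C_cat[, e$category],
        valence_slope = mag * M_val,
        ppi_gain = mag * ppi_bold[[as.character(e$seed_id)]] +
          config$connectivity$baseline_gain * seed_bold[[as.character(e$seed_id)]]
      )
      mean_signal[, p] <- mean_signal[, p] + add
    }
  }

  # voxel expansion: per-voxel gain on the task part, drift, AR(1) noise
  V <- config$voxels_per_parcel
  nz <- config$noise
  t_s <- (seq_len(n_vol) - 1) * tr
  total_vox <- config$n_parcels * V
  gains <- 1 + stats::rnorm(total_vox, 0, config$voxel_gain_sd)
  phases <- stats::runif(total_vox, 0, 2 * pi)
  innov_sd <- nz$white_sd * sqrt(1 - nz$ar1^2)
  noise <- matrix(stats::rnorm(n_vol * total_vox, 0, innov_sd), n_vol, total_vox)
  if (nz$ar1 != 0 && nz$white_sd > 0) {
    noise <- apply(noise, 2L, function(e) {
      as.numeric(stats::filter(e, nz$ar1, method = "recursive"))
    })
  }
  task_part <- mean_signal - config$baseline
  data <- matrix(0, n_vol, total_vox)
  for (p in seq_len(config$n_parcels)) {
    cols <- ((p - 1) * V + 1):(p * V)
    drift <- if (nz$drift_amplitude > 0) {
      vapply(phases[cols], function(ph) {
        nz$drift_amplitude * sin(2 * pi * t_s / nz$drift_period_s + ph)
      }, numeric(n_vol))
    } else matrix(0, n_vol, V)
    data[, cols] <- config$baseline +
      outer(task_part[, p], gains[cols]) + drift + noise[, cols, drop = FALSE]
  }
  parcel_ts(data, tr_s = tr,
            voxel_map = tibble::tibble(
              parcel_id = rep(seq_len(config$n_parcels), each = V),
              voxel = rep(seq_len(V), config$n_parcels)))
}

#' Simulate a full two-group cohort
#'
#' Draws subject metadata (balanced sex, age, BDI-2, IAPS set, recognition
#' outcomes), per-subject events, motion parameters and parcel time series.
#' The root seed spawns one child seed per subject, so cohorts are
#' bit-identical under a fixed root seed, and the returned manifest records
#' the planted ground truth for recovery scoring.
#'
#' @param config A [sim_config()].
#' @param atlas Atlas lookup (defaults to [default_atlas()] of matching
#'   size).
#' @param simulate_ts If `FALSE`, skip the (expensive) BOLD simulation and
#'   return events/metadata only -- useful for behavioural analyses.
#' @return A `bold_cohort`: list with `subjects` (tibble incl. list-columns
#'   `events` and `motion`), `ts` (list of [parcel_ts()] keyed by subject
#'   id), `atlas`, `manifest` and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), atlas = NULL,
                            simulate_ts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(atlas)) atlas <- default_atlas(config$n_parcels)
  n <- config$n_per_group
  cm <- config$covariate_model
  ids <- sprintf("sub%02d", seq_len(2L * n))
  groups <- rep(c("PATIENT", "HC"), each = n)
  seeds <- child_seeds(config$seed, 2L * n + 1L)

  meta <- withr::with_seed(seeds[2L * n + 1L], {
    tibble::tibble(
      subject_id = ids, group = groups,
      sex = unlist(lapply(1:2, function(g) sample(rep(c("F", "M"), length.out = n)))),
      age = round(pmax(18, stats::rnorm(2 * n, cm$age_mean, cm$age_sd)), 1),
      bdi2 = round(pmax(0, stats::rnorm(2 * n, cm$bdi_mean, cm$bdi_sd)), 1),
      iaps_set = unlist(lapply(1:2, function(g) sample(rep(c("A", "B"), length.out = n)))),
      recognition_performance = pmin(100, stats::rnorm(2 * n, cm$recognition_mean,
                                                       cm$recognition_sd)),
      recognition_rt = pmax(200, stats::rnorm(2 * n, cm$rt_mean, cm$rt_sd))
    )
  })
  events <- vector("list", 2L * n)
  motion <- vector("list", 2L * n)
  ts <- if (simulate_ts) vector("list", 2L * n) else NULL
  for (i in seq_len(2L * n)) {
    withr::with_seed(seeds[i], {
      events[[i]] <- simulate_events(config, groups[i])
      motion[[i]] <- matrix(c(
        replicate(3, cumsum(stats::rnorm(config$n_volumes, 0, 0.02))),
        replicate(3, cumsum(stats::rnorm(config$n_volumes, 0, 5e-4)))),
        ncol = 6)
      if (simulate_ts) {
        ts[[i]] <- simulate_subject(config, groups[i], events[[i]], atlas)
      }
    })
  }
  meta$events <- events
  meta$motion <- motion
  if (simulate_ts) names(ts) <- ids
  manifest <- list(
    seed = config$seed,
    n_per_group = n,
    effects = purrr::map_dfr(config$effects, function(e) {
      tibble::tibble(kind = e$kind, group = e$group, magnitude = e$magnitude,
                     seed_id = e$seed_id, category = e$category,
                     parcel_ids = list(e$parcel_ids))
    })
  )
  structure(list(subjects = meta, ts = ts, atlas = atlas,
                 manifest = manifest, config = config),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  cat(sprintf("<bold_cohort> %d subjects (%d per group), %d parcels%s\n",
              nrow(x$subjects), x$config$n_per_group, x$config$n_parcels,
              if (is.null(x$ts)) " [metadata only]" else ""))
  cat(sprintf("  planted effects: %d\n", length(x$config$effects)))
  invisible(x)
}

#' Write a cohort to disk as plain-text artefacts
#'
#' Emits one BIDS-style events TSV and one parcel-matrix TSV (+ sidecar) per
#' subject, a covariate table, and a JSON manifest of the planted ground
#' truth.
#'
#' @param cohort A `bold_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bold_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject_id[i]
    write_events(cohort$subjects$events[[i]],
                 file.path(dir, paste0(id, "_events.tsv")))
    if (!is.null(cohort$ts)) {
      write_parcel_matrix(cohort$ts[[id]],
                          file.path(dir, paste0(id, "_parcels.tsv")))
    }
  }
  readr::write_tsv(cohort$subjects[, setdiff(names(cohort$subjects),
                                             c("events", "motion"))],
                   file.path(dir, "participants.tsv"), progress = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Long-format behavioural table
#'
#' Collapses a cohort's trial-level ratings to the per-subject endpoint
#' tables consumed by [behavioral_analysis()]: mean valence rating per
#' picture category, mean arousal rating per arousal class, or the scalar
#' recognition outcomes (no within-subject factor).
#'
#' @param cohort A `bold_cohort`.
#' @param outcome One of `"valence"`, `"arousal"`,
#'   `"recognition_performance"`, `"recognition_rt"`.
#' @return A tibble with columns `subject_id`, `group`, the covariates,
#'   `level` (within-factor level, `NA` for recognition outcomes) and
#'   `response`.
#' @export
behavioral_table <- function(cohort, outcome = c("valence", "arousal",
                                                 "recognition_performance",
                                                 "recognition_rt")) {
  outcome <- match.arg(outcome)
  meta <- cohort$subjects[, c("subject_id", "group", "sex", "age", "bdi2",
                              "iaps_set")]
  if (outcome %in% c("recognition_performance", "recognition_rt")) {
    out <- meta
    out$level <- NA_character_
    out$response <- cohort$subjects[[outcome]]
    return(out)
  }
  key <- if (outcome == "valence") "category" else "arousal_class"
  val <- if (outcome == "valence") "valence_rating" else "arousal_rating"
  purrr::map_dfr(seq_len(nrow(cohort$subjects)), function(i) {
    ev <- cohort$subjects$events[[i]]
    agg <- tapply(ev[[val]], ev[[key]], mean)
    out <- meta[rep(i, length(agg)), ]
    out$level <- names(agg)
    out$response <- as.numeric(agg)
    out
  })
}
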