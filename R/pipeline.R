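# End-to-end conveniences tying the stages together for a simulated (or
# imported) cohort.

#' Per-subject first-level fits and contrast extraction for a cohort
#'
#' Runs, for every subject: design construction (category, rating-modulated
#' or PPI model), discrete-cosine high-pass filtering, the AR(1)-ReML GLM,
#' and the requested contrast; then collapses voxels to parcel medians.
#'
#' @param cohort A `bold_cohort` with time series.
#' @param model `"category"` (uniform-amplitude category boxcars),
#'   `"valence"`/`"arousal"` (rating-modulated), or `"ppi"`.
#' @param contrast Contrast specification (default depends on model:
#'   `"NEG - NEU"`, `"VAL"`, `"ARO"`, or the NEG-NEU PPI column).
#' @param seed_id Seed parcel for `model = "ppi"` (defaults to the atlas's
#'   right seed).
#' @param cutoff_hz High-pass cutoff (default 1/128).
#' @param endpoint Label for the resulting estimates.
#' @return A `parcel_estimates` tibble (subject x parcel medians).
#' @export
cohort_contrasts <- function(cohort, model = c("category", "valence",
                                               "arousal", "ppi"),
                             contrast = NULL, seed_id = NULL,
                             cutoff_hz = 1 / 128, endpoint = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "bold_cohort"), !is.null(cohort$ts))
  cfg <- cohort$config
  if (model == "ppi" && is.null(seed_id)) {
    seeds <- cohort$atlas$parcel_id[cohort$atlas$is_seed]
    seed_id <- seeds[length(seeds)]
  }
  contrast <- contrast %||% switch(model, category = "NEG - NEU",
                                   valence = "VAL", arousal = "ARO",
                                   ppi = "PPI_NEG-NEU")
  endpoint <- endpoint %||% switch(model, category = "dBR_N",
                                   valence = "slope_VAL",
                                   arousal = "slope_ARO",
                                   ppi = paste0("dFC_seed", seed_id))
  per_subject <- purrr::map_dfr(seq_len(nrow(cohort$subjects)), function(i) {
    id <- cohort$subjects$subject_id[i]
    ev <- cohort$subjects$events[[i]]
    mo <- cohort$subjects$motion[[i]]
    ts <- cohort$ts[[id]]
    cc <- if (model == "ppi") {
      ts_f <- dct_highpass(ts, cutoff_hz = cutoff_hz)
      seed <- extract_eigenvariate(ts_f, seed_id)
      d <- build_ppi_design(ev, seed, mo, cfg$n_volumes, cfg$tr_s,
                            bins = cfg$bins_per_tr)
      estimate_fc_contrasts(dct_highpass(d, cutoff_hz = cutoff_hz), ts,
                            column = contrast)
    } else {
      d <- if (model == "category") {
        build_model1_design(ev, mo, cfg$n_volumes, cfg$tr_s,
                            bins = cfg$bins_per_tr)
      } else {
        build_model2_design(ev, mo, cfg$n_volumes, cfg$tr_s,
                            bins = cfg$bins_per_tr)
      }
      fit <- fit_glm(dct_highpass(d, cutoff_hz = cutoff_hz), ts)
      compute_contrast(fit, contrast)
    }
    cc$subject_id <- id
    tibble::as_tibble(cc)
  })
  atlas <- cohort$atlas
  if (model == "ppi") atlas <- atlas[atlas$parcel_id != seed_id, ]
  extract_parcel_medians(per_subject, atlas = atlas, endpoint = endpoint)
}

#' Full parcel-wise group analysis of a cohort
#'
#' Chains [cohort_contrasts()], [adjust_covariates()] and [test_regions()]:
#' per-subject GLM contrasts, parcel medians, nuisance-covariate adjustment
#' and the dual-threshold Bayesian region decisions.
#'
#' @inheritParams cohort_contrasts
#' @param covariates Covariates removed before group testing (default sex,
#'   age, BDI-2); `NULL` skips adjustment.
#' @param ... Passed to [test_regions()].
#' @return A list with `estimates` (adjusted `parcel_estimates`) and
#'   `decisions` (`region_decisions`).
#' @export
run_parcel_analysis <- function(cohort, model = "category", contrast = NULL,
                                seed_id = NULL,
                                covariates = c("sex", "age", "bdi2"), ...) {
  est <- cohort_contrasts(cohort, model = model, contrast = contrast,
                          seed_id = seed_id)
  if (!is.null(covariates)) {
    est <- adjust_covariates(est, cohort$subjects, covariates)
  }
  dec <- test_regions(est, cohort$subjects, ...)
  list(estimates = est, decisions = dec)
}
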