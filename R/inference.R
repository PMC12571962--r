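# Group-level pipeline: parcel medians, covariate adjustment, region-wise
# Bayes-factor testing with the dual-threshold selection rule, behavioural
# ANCOVAs and report rendering.

#' Median contrast estimate per subject and parcel
#'
#' Collapses voxel-level contrast values to one robust estimate per subject
#' and parcel (the median over the parcel's voxels).
#'
#' @param contrasts A data frame with columns `parcel_id`, `value` and
#'   optionally `subject_id` (added as `"s1"` when absent) -- e.g. a
#'   [compute_contrast()] result or several of them row-bound with a subject
#'   column.
#' @param atlas Optional atlas lookup; parcels listed there but missing from
#'   `contrasts` are filled with `NA` and flagged with a warning.
#' @param endpoint Label stored with the result (e.g. `"dBR_N"`).
#' @return A tibble of class `parcel_estimates` with columns `subject_id`,
#'   `parcel_id`, `estimate`; attribute `adjusted` is `FALSE`.
#' @export
extract_parcel_medians <- function(contrasts, atlas = NULL,
                                   endpoint = "contrast") {
  df <- tibble::as_tibble(contrasts)
  if (!"subject_id" %in% names(df)) df$subject_id <- "s1"
  if (!all(c("parcel_id", "value") %in% names(df))) {
    abort_argument("`contrasts` needs columns parcel_id and value")
  }
  out <- df |>
    dplyr::group_by(.data$subject_id, .data$parcel_id) |>
    dplyr::summarise(estimate = stats::median(.data$value), .groups = "drop")
  if (!is.null(atlas)) {
    missing <- setdiff(atlas$parcel_id, unique(out$parcel_id))
    if (length(missing)) {
      warning(sprintf("%d parcel(s) have no voxels; estimates set to NA",
                      length(missing)), call. = FALSE)
      out <- tidyr::complete(out, subject_id = unique(out$subject_id),
                             parcel_id = atlas$parcel_id)
    }
  }
  structure(out, endpoint = endpoint, adjusted = FALSE,
            class = c("parcel_estimates", class(out)))
}

#' Adjust parcel estimates for nuisance covariates
#'
#' Residualises each parcel's cross-subject estimates on the given
#' covariates plus an intercept, pooling both groups WITHOUT a group term so
#' that genuine group differences survive adjustment, and restores the
#' parcel mean so group means remain interpretable. Collinear covariates are
#' dropped with a warning.
#'
#' @param estimates A `parcel_estimates` tibble.
#' @param subjects Subject metadata with `subject_id` and the covariate
#'   columns.
#' @param covariates Covariate column names (default sex, age, BDI-2).
#' @return The adjusted `parcel_estimates` (attribute `adjusted = TRUE`).
#' @export
adjust_covariates <- function(estimates, subjects,
                              covariates = c("sex", "age", "bdi2")) {
  df <- dplyr::left_join(tibble::as_tibble(estimates),
                         subjects[, c("subject_id", covariates)],
                         by = "subject_id")
  sub <- df[!duplicated(df$subject_id), c("subject_id", covariates), drop = FALSE]
  X <- stats::model.matrix(~., data = sub[, covariates, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-seq_len(qrX$rank)]
    warning(paste0("collinear covariate column(s) dropped: ",
                   paste(drop, collapse = ", ")), call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  rownames(X) <- sub$subject_id
  out <- tibble::as_tibble(estimates) |>
    dplyr::group_by(.data$parcel_id) |>
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$estimate)
      if (sum(ok) > ncol(X)) {
        Xs <- X[d$subject_id[ok], , drop = FALSE]
        res <- stats::lsfit(Xs, d$estimate[ok], intercept = FALSE)$residuals
        d$estimate[ok] <- res + mean(d$estimate[ok])
      }
      d
    }) |>
    dplyr::ungroup()
  structure(out, endpoint = attr(estimates, "endpoint"), adjusted = TRUE,
            covariates = covariates,
            class = c("parcel_estimates", class(out)))
}

#' Region-wise Bayesian group tests with the dual-threshold rule
#'
#' For every parcel: a two-sided JZS independent-samples Bayes factor on the
#' group difference of the (adjusted) estimates, and four one-sided
#' one-sample Bayes factors (each group x each direction) for the group-wise
#' main effects. The verdict is `difference` when the group-difference
#' `log10(BF10)` exceeds `diff_threshold` (strong evidence), `similarity`
#' when it falls below `similarity_threshold` (moderate evidence for H0),
#' otherwise `undecided`. A difference parcel is flagged `reported` only if
#' additionally at least one group shows at least moderate one-sided
#' main-effect evidence (`max one-sided log10 BF > main_threshold`), which
#' screens out group differences without a sufficient main effect.
#'
#' @param estimates A `parcel_estimates` tibble.
#' @param subjects Subject metadata with `subject_id` and `group`.
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @param diff_threshold,similarity_threshold,main_threshold Rule thresholds
#'   on the log10 scale (defaults 1.0, -0.5, 0.5).
#' @return A tibble of class `region_decisions`, one row per parcel, with the
#'   group-difference BF, the four one-sided BFs, per-group means/SDs,
#'   `verdict`, `reported` and `evidence` grade.
#' @export
test_regions <- function(estimates, subjects, r = sqrt(2) / 2,
                         diff_threshold = 1, similarity_threshold = -0.5,
                         main_threshold = 0.5) {
  df <- dplyr::left_join(tibble::as_tibble(estimates),
                         subjects[, c("subject_id", "group")],
                         by = "subject_id")
  groups <- sort(unique(df$group))
  if (length(groups) != 2L) abort_argument("need exactly two groups")
  g1 <- groups[1]; g2 <- groups[2]
  one_sided <- function(x, direction) {
    tryCatch(jzs_one_sample_bf(x, r = r, direction = direction)$log10_bf10,
             error = function(e) NA_real_)
  }
  out <- df |>
    dplyr::group_by(.data$parcel_id) |>
    dplyr::group_modify(function(d, key) {
      x1 <- d$estimate[d$group == g1]
      x2 <- d$estimate[d$group == g2]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
      degenerate <- length(x1) < 2 || length(x2) < 2 ||
        stats::sd(c(x1, x2)) == 0 || stats::sd(x1) == 0 || stats::sd(x2) == 0
      if (degenerate) {
        return(tibble::tibble(
          n_1 = length(x1), n_2 = length(x2),
          mean_1 = mean(x1), sd_1 = stats::sd(x1),
          mean_2 = mean(x2), sd_2 = stats::sd(x2),
          log10_bf_diff = NA_real_,
          log10_bf_1_greater = NA_real_, log10_bf_1_less = NA_real_,
          log10_bf_2_greater = NA_real_, log10_bf_2_less = NA_real_,
          verdict = "undecided", reported = FALSE, degenerate = TRUE))
      }
      bf_diff <- jzs_two_sample_bf(x1, x2, r = r)$log10_bf10
      b1g <- one_sided(x1, "greater"); b1l <- one_sided(x1, "less")
      b2g <- one_sided(x2, "greater"); b2l <- one_sided(x2, "less")
      verdict <- if (bf_diff > diff_threshold) "difference"
        else if (bf_diff < similarity_threshold) "similarity"
        else "undecided"
      main_ok <- max(b1g, b1l, b2g, b2l, na.rm = TRUE) > main_threshold
      tibble::tibble(
        n_1 = length(x1), n_2 = length(x2),
        mean_1 = mean(x1), sd_1 = stats::sd(x1),
        mean_2 = mean(x2), sd_2 = stats::sd(x2),
        log10_bf_diff = bf_diff,
        log10_bf_1_greater = b1g, log10_bf_1_less = b1l,
        log10_bf_2_greater = b2g, log10_bf_2_less = b2l,
        verdict = verdict,
        reported = verdict == "difference" && main_ok,
        degenerate = FALSE)
    }) |>
    dplyr::ungroup()
  out$evidence <- ifelse(is.na(out$log10_bf_diff), NA_character_,
                         grade_evidence(dplyr::coalesce(out$log10_bf_diff, 0)))
  structure(out, groups = groups, endpoint = attr(estimates, "endpoint"),
            thresholds = c(difference = diff_threshold,
                           similarity = similarity_threshold,
                           main_effect = main_threshold),
            prior_scale_r = r,
            class = c("region_decisions", class(out)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.region_decisions <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$parcel_id, .data$log10_bf_diff,
                                   colour = .data$verdict)) +
    ggplot2::geom_hline(yintercept = c(th[["difference"]], th[["similarity"]]),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(difference = "firebrick",
                                            similarity = "steelblue",
                                            undecided = "grey60")) +
    ggplot2::labs(x = "parcel", y = expression(log[10] ~ BF[10]),
                  title = "Group-difference evidence by parcel")
}

#' Behavioural endpoint analysis
#'
#' Runs the 2-way Bayesian repeated-measures ANCOVA (between-subject factor
#' group, within-subject factor stimulus category) on a long behavioural
#' table and, when the group-by-category interaction earns at least moderate
#' inclusion evidence, follows up with one-sided two-sample Bayes factors per
#' category level in the direction of the observed group difference.
#'
#' @param behav Long table as produced by [behavioral_table()].
#' @param covariates Nuisance covariates present in `behav`.
#' @param posthoc_threshold Interaction inclusion threshold gating the
#'   post-hoc tests (log10 scale, default 0.5).
#' @inheritParams rmancova_inclusion_bf
#' @return A list of class `behavioral_result` with `inclusion` (predictor
#'   inclusion BFs) and `posthoc` (possibly empty tibble of directional
#'   group comparisons per level).
#' @export
behavioral_analysis <- function(behav, covariates = c("age", "sex",
                                                      "iaps_set", "bdi2"),
                                mcmc_passes = 5000, seed = NULL,
                                posthoc_threshold = 0.5,
                                r_fixed = sqrt(2) / 2) {
  has_within <- !all(is.na(behav$level))
  fit <- rmancova_inclusion_bf(
    behav, response = "response", subject = "subject_id",
    within = if (has_within) "level" else NULL, between = "group",
    covariates = covariates, mcmc_passes = mcmc_passes, seed = seed,
    r_fixed = r_fixed)
  posthoc <- tibble::tibble(level = character(), direction = character(),
                            log10_bf = numeric())
  ix <- fit$inclusion$log10_bf_incl[fit$inclusion$predictor == "interaction"]
  if (has_within && length(ix) && is.finite(ix) && ix > posthoc_threshold) {
    groups <- sort(unique(behav$group))
    posthoc <- purrr::map_dfr(unique(behav$level), function(lv) {
      d <- behav[behav$level == lv, ]
      x1 <- d$response[d$group == groups[1]]
      x2 <- d$response[d$group == groups[2]]
      dir <- if (mean(x1) >= mean(x2)) "greater" else "less"
      bf <- jzs_two_sample_bf(x1, x2, r = r_fixed, direction = dir)
      tibble::tibble(
        level = lv,
        direction = paste(groups[if (dir == "greater") c(1, 2) else c(2, 1)],
                          collapse = " > "),
        log10_bf = bf$log10_bf10)
    })
  }
  structure(list(inclusion = fit$inclusion, posthoc = posthoc,
                 fit = fit), class = "behavioral_result")
}

#' @export
print.behavioral_result <- function(x, ...) {
  cat("<behavioral_result> inclusion Bayes factors:\n")
  print(as.data.frame(x$inclusion), row.names = FALSE)
  if (nrow(x$posthoc)) {
    cat("post-hoc one-sided group comparisons:\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Render a region-decision report
#'
#' Writes the decisions as a machine-readable TSV and a human-readable text
#' report laid out like a results table: difference regions ordered by
#' descending absolute group-difference evidence, with the per-group
#' one-sided Bayes factors and mean +/- SD, followed by a separate section
#' listing the similarity regions.
#'
#' @param decisions A `region_decisions` tibble.
#' @param atlas Optional atlas lookup providing region names/hemispheres.
#' @param endpoint Label used in headers and file names.
#' @param dir Output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
render_report <- function(decisions, atlas = NULL, endpoint = NULL, dir = ".") {
  endpoint <- endpoint %||% attr(decisions, "endpoint") %||% "contrast"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- tibble::as_tibble(decisions)
  if (!is.null(atlas)) {
    df <- dplyr::left_join(df, atlas[, c("parcel_id", "name", "hemisphere")],
                           by = "parcel_id")
  }
  df <- df[order(-abs(dplyr::coalesce(df$log10_bf_diff, 0))), ]
  tsv <- file.path(dir, paste0(endpoint, "_regions.tsv"))
  txt <- file.path(dir, paste0(endpoint, "_report.txt"))
  readr::write_tsv(df, tsv, progress = FALSE)

  groups <- attr(decisions, "groups") %||% c("group1", "group2")
  fmt_row <- function(r) {
    nm <- if (!is.null(r$name)) sprintf("%-22s %s", r$name, r$hemisphere)
          else sprintf("parcel %3d", r$parcel_id)
    sprintf("  %s  diff %6.3f  %s %6.3f | %6.3f (%.3f +/- %.3f)  %s %6.3f | %6.3f (%.3f +/- %.3f)%s",
            nm, r$log10_bf_diff,
            groups[1], r$log10_bf_1_greater, r$log10_bf_1_less, r$mean_1, r$sd_1,
            groups[2], r$log10_bf_2_greater, r$log10_bf_2_less, r$mean_2, r$sd_2,
            if (isTRUE(r$reported)) "  *reported*" else "")
  }
  lines <- c(sprintf("Endpoint: %s", endpoint),
             sprintf("Selection rule: difference if log10 BF10 > %.2f; reported if additionally max one-sided main-effect log10 BF > %.2f; similarity if log10 BF10 < %.2f",
                     attr(decisions, "thresholds")[["difference"]] %||% 1,
                     attr(decisions, "thresholds")[["main_effect"]] %||% 0.5,
                     attr(decisions, "thresholds")[["similarity"]] %||% -0.5),
             "", "== Group differences (H1 preferred) ==")
  diffs <- df[df$verdict == "difference" & !is.na(df$verdict), ]
  if (nrow(diffs)) {
    lines <- c(lines, vapply(seq_len(nrow(diffs)),
                             function(i) fmt_row(diffs[i, ]), character(1)))
  } else lines <- c(lines, "  (none)")
  lines <- c(lines, "", "== Group similarities (H0 preferred) ==")
  sims <- df[df$verdict == "similarity" & !is.na(df$verdict), ]
  if (nrow(sims)) {
    lines <- c(lines, vapply(seq_len(nrow(sims)),
                             function(i) fmt_row(sims[i, ]), character(1)))
  } else lines <- c(lines, "  (none)")
  writeLines(lines, txt)
  invisible(c(tsv = tsv, txt = txt))
}
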