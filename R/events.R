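#' Per-trial event table for the emotional-picture paradigm
#'
#' Validates and classes a data frame of trial events: picture onsets and
#' durations, the NEG/NEU/POS valence category and LOW/HIGH arousal class of
#' each picture, the subject's 9-level SAM valence and arousal ratings, the
#' rating epoch, and the times of rating button presses.
#'
#' @param x A data frame with columns `trial_id`, `onset_s`,
#'   `picture_duration_s`, `category`, `arousal_class`, `valence_rating`,
#'   `arousal_rating`, `rating_onset_s`, `rating_duration_s` and (optionally)
#'   the list-column `button_press_times_s`. Extra columns are preserved.
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("trial_id", "onset_s", "picture_duration_s", "category",
                "arousal_class", "valence_rating", "arousal_rating",
                "rating_onset_s", "rating_duration_s")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_format(paste0("event table is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"button_press_times_s" %in% names(x)) {
    x$button_press_times_s <- replicate(nrow(x), numeric(0), simplify = FALSE)
  }
  if (nrow(x) > 1 && any(diff(x$onset_s) <= 0)) {
    abort_validation("picture onsets must be strictly increasing")
  }
  if (!all(x$category %in% c("NEG", "NEU", "POS"))) {
    abort_validation("`category` must be one of NEG, NEU, POS")
  }
  if (!all(x$arousal_class %in% c("LOW", "HIGH"))) {
    abort_validation("`arousal_class` must be LOW or HIGH")
  }
  ratings <- c(x$valence_rating, x$arousal_rating)
  if (any(!is.finite(ratings)) || any(ratings < 1 | ratings > 9)) {
    abort_validation("SAM ratings must lie in 1..9")
  }
  if (any(x$rating_duration_s < 0 | x$rating_duration_s > 8)) {
    abort_validation("rating durations must lie in [0, 8] s")
  }
  class(x) <- c("event_table", class(tibble::tibble()))
  x
}

#' Read a BIDS-style events file
#'
#' Reads a tab-separated events file with the BIDS dialect columns `onset`,
#' `duration`, `trial_type`, `valence_rating`, `arousal_rating` (plus the
#' optional columns written by [write_events()]) and returns a validated
#' [event_table()]. Unknown columns are carried along unchanged.
#'
#' @param path Path to a tab-separated events file.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  x <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste0("cannot parse events file: ",
                                            conditionMessage(e)))
  )
  required <- c("onset", "duration", "trial_type",
                "valence_rating", "arousal_rating")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_format(paste0("events file is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    trial_id = if ("trial_id" %in% names(x)) x$trial_id else seq_len(nrow(x)),
    onset_s = x$onset,
    picture_duration_s = x$duration,
    category = x$trial_type,
    arousal_class = if ("arousal_class" %in% names(x)) x$arousal_class
                    else rep(NA_character_, nrow(x)),
    valence_rating = x$valence_rating,
    arousal_rating = x$arousal_rating,
    rating_onset_s = if ("rating_onset" %in% names(x)) x$rating_onset
                     else x$onset + x$duration,
    rating_duration_s = if ("rating_duration" %in% names(x)) x$rating_duration
                        else 0
  )
  out$button_press_times_s <- if ("button_press_times" %in% names(x)) {
    lapply(x$button_press_times, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  } else {
    replicate(nrow(out), numeric(0), simplify = FALSE)
  }
  extra <- setdiff(names(x), c(required, "trial_id", "arousal_class",
                               "rating_onset", "rating_duration",
                               "button_press_times"))
  for (col in extra) out[[col]] <- x[[col]]
  event_table(out)
}

#' Write an event table as a BIDS-style TSV
#'
#' Inverse of [read_events()]: the written file round-trips through
#' [read_events()] up to floating-point formatting.
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- event_table(events)
  out <- tibble::tibble(
    onset = events$onset_s,
    duration = events$picture_duration_s,
    trial_type = events$category,
    trial_id = events$trial_id,
    arousal_class = events$arousal_class,
    valence_rating = events$valence_rating,
    arousal_rating = events$arousal_rating,
    rating_onset = events$rating_onset_s,
    rating_duration = events$rating_duration_s,
    button_press_times = vapply(events$button_press_times_s,
                                function(v) paste(format(v, digits = 15, trim = TRUE),
                                                  collapse = ","),
                                character(1))
  )
  extra <- setdiff(names(events),
                   c("trial_id", "onset_s", "picture_duration_s", "category",
                     "arousal_class", "valence_rating", "arousal_rating",
                     "rating_onset_s", "rating_duration_s",
                     "button_press_times_s"))
  for (col in extra) out[[col]] <- events[[col]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.event_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_s,
                                       xend = .data$onset_s + .data$picture_duration_s,
                                       y = .data$category, yend = .data$category,
                                       colour = .data$category),
                          linewidth = 4, show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Trial timeline")
}
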