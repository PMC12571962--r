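# First-level design construction: microtime neural regressors, canonical-HRF
# convolution, downsampling to volume times, and the discrete-cosine high-pass.

# --- microtime helpers -------------------------------------------------------

micro_length <- function(n_volumes, bins) n_volumes * bins

# indices (1-based) of the middle microtime bin of each volume
micro_sample_index <- function(n_volumes, bins) {
  (seq_len(n_volumes) - 1L) * bins + bins %/% 2L + 1L
}

# boxcar neural signal on the microtime grid; amplitudes recycle over epochs
neural_boxcar <- function(onsets, durations, n_micro, dt, amplitudes = 1) {
  amplitudes <- rep_len(amplitudes, length(onsets))
  z <- numeric(n_micro)
  for (i in seq_along(onsets)) {
    from <- floor(onsets[i] / dt) + 1L
    to <- min(n_micro, floor((onsets[i] + durations[i]) / dt))
    if (from <= to) z[from:to] <- z[from:to] + amplitudes[i]
  }
  z
}

# unit impulses at event times on the microtime grid
neural_sticks <- function(times, n_micro, dt) {
  z <- numeric(n_micro)
  idx <- floor(times / dt) + 1L
  idx <- idx[idx >= 1L & idx <= n_micro]
  for (i in idx) z[i] <- z[i] + 1
  z
}

# convolve a microtime neural signal with the HRF and sample at volume times
convolve_regressor <- function(neural, hrf, n_volumes, bins) {
  full <- convolve_open(neural, hrf$values)[seq_along(neural)]
  full[micro_sample_index(n_volumes, bins)]
}

# linear ("open") convolution via FFT, truncated to length(x) + length(k) - 1
convolve_open <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nfft <- stats::nextn(n, 2L)
  xf <- stats::fft(c(x, numeric(nfft - length(x))))
  kf <- stats::fft(c(k, numeric(nfft - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_len(n)] / nfft
}

# --- design matrix container -------------------------------------------------

new_design_matrix <- function(matrix, roles, tr_s, n_volumes, bins, hrf,
                              notes = character(0)) {
  stopifnot(ncol(matrix) == length(roles))
  structure(
    list(matrix = matrix, column_names = colnames(matrix),
         column_roles = roles, tr_s = tr_s, n_volumes = n_volumes,
         bins = bins, hrf = hrf,
         highpass = list(applied = FALSE, cutoff_hz = NA_real_),
         non_estimable = colnames(matrix)[apply(matrix, 2, function(v) all(v == 0))],
         notes = notes),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d columns (TR = %g s)\n",
              x$n_volumes, ncol(x$matrix), x$tr_s))
  cat("  roles: ", paste(sprintf("%s[%s]", x$column_names, x$column_roles),
                         collapse = " "), "\n", sep = "")
  if (x$highpass$applied) {
    cat(sprintf("  high-pass applied (cutoff %.5f Hz)\n", x$highpass$cutoff_hz))
  }
  if (length(x$non_estimable)) {
    cat("  non-estimable columns:", paste(x$non_estimable, collapse = ", "), "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.design_matrix <- function(x, ...) {
  tibble::tibble(
    volume = rep(seq_len(x$n_volumes), times = ncol(x$matrix)),
    time_s = (rep(seq_len(x$n_volumes), times = ncol(x$matrix)) - 1) * x$tr_s,
    column = rep(x$column_names, each = x$n_volumes),
    role = rep(x$column_roles, each = x$n_volumes),
    value = as.vector(x$matrix)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.design_matrix <- function(object, ...) {
  df <- tidy.design_matrix(object)
  df$column <- factor(df$column, levels = object$column_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~column, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Design matrix columns")
}

check_motion <- function(motion, n_volumes) {
  if (is.null(motion)) motion <- matrix(0, n_volumes, 6)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes || ncol(motion) != 6L) {
    abort_validation("`motion` must be an n_volumes x 6 matrix")
  }
  colnames(motion) <- paste0("motion", 1:6)
  motion
}

press_regressor <- function(events, n_micro, dt, hrf, n_volumes, bins) {
  times <- unlist(events$button_press_times_s, use.names = FALSE)
  convolve_regressor(neural_sticks(times, n_micro, dt), hrf, n_volumes, bins)
}

#' Category design matrix (uniform-amplitude boxcars)
#'
#' Builds the first-level design for the category analysis: one unit-amplitude
#' boxcar regressor per picture category (NEG, NEU, POS; 6 s epochs by
#' default), one stick-function regressor collecting all rating button
#' presses, six motion regressors of no interest, and a constant. Neural
#' regressors are built on a microtime grid, convolved with the canonical HRF
#' and sampled at the middle microtime bin of each volume.
#'
#' @param events An [event_table()].
#' @param motion `n_volumes x 6` motion-parameter matrix (or `NULL` for
#'   zeros).
#' @param n_volumes,tr_s Number of acquired volumes and repetition time.
#' @param hrf An [canonical_hrf()] kernel sampled at `tr_s / bins`; built
#'   automatically when `NULL`.
#' @param bins Microtime bins per TR (default 16).
#' @return A `design_matrix` with column roles
#'   `task, press, motion, constant`.
#' @export
build_model1_design <- function(events, motion = NULL, n_volumes, tr_s,
                                hrf = NULL, bins = 16L) {
  events <- event_table(events)
  motion <- check_motion(motion, n_volumes)
  dt <- tr_s / bins
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  n_micro <- micro_length(n_volumes, bins)
  notes <- character(0)
  cats <- c("NEG", "NEU", "POS")
  task <- sapply(cats, function(cc) {
    ev <- events[events$category == cc, ]
    if (nrow(ev) == 0L) {
      notes <<- c(notes, sprintf("category %s absent from events; column is zero and non-estimable", cc))
      return(numeric(n_volumes))
    }
    convolve_regressor(
      neural_boxcar(ev$onset_s, ev$picture_duration_s, n_micro, dt),
      hrf, n_volumes, bins)
  })
  press <- press_regressor(events, n_micro, dt, hrf, n_volumes, bins)
  X <- cbind(task, press = press, motion, constant = 1)
  colnames(X) <- c(cats, "press", colnames(motion), "constant")
  roles <- c(rep("task", 3), "press", rep("motion", 6), "constant")
  d <- new_design_matrix(X, roles, tr_s, n_volumes, bins, hrf, notes)
  d$non_estimable <- setdiff(d$non_estimable, "constant")
  if (length(notes)) warning(paste(notes, collapse = "; "), call. = FALSE)
  d
}

#' Rating-modulated design matrix (parametric valence/arousal)
#'
#' Builds the parametric first-level design: a mean picture-epoch boxcar, a
#' valence-modulated epoch regressor whose per-trial amplitude is the
#' subject's SAM valence rating centred on the run mean, an arousal-modulated
#' regressor built the same way, plus press, motion and constant columns. The
#' two modulators are mean-centred but deliberately not orthogonalised against
#' each other.
#'
#' @inheritParams build_model1_design
#' @return A `design_matrix` with roles
#'   `task, parametric, parametric, press, motion, constant`.
#' @export
build_model2_design <- function(events, motion = NULL, n_volumes, tr_s,
                                hrf = NULL, bins = 16L) {
  events <- event_table(events)
  if (any(is.na(events$valence_rating)) || any(is.na(events$arousal_rating))) {
    abort_validation("all trials must carry valence and arousal ratings")
  }
  motion <- check_motion(motion, n_volumes)
  dt <- tr_s / bins
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  n_micro <- micro_length(n_volumes, bins)
  notes <- character(0)
  mean_col <- convolve_regressor(
    neural_boxcar(events$onset_s, events$picture_duration_s, n_micro, dt),
    hrf, n_volumes, bins)
  modulated <- function(ratings, label) {
    amp <- ratings - mean(ratings)
    if (all(amp == 0)) {
      notes <<- c(notes, sprintf("constant %s ratings; modulator column is zero and non-estimable", label))
      return(numeric(n_volumes))
    }
    convolve_regressor(
      neural_boxcar(events$onset_s, events$picture_duration_s, n_micro, dt,
                    amplitudes = amp),
      hrf, n_volumes, bins)
  }
  val <- modulated(events$valence_rating, "valence")
  aro <- modulated(events$arousal_rating, "arousal")
  press <- press_regressor(events, n_micro, dt, hrf, n_volumes, bins)
  X <- cbind(mean_col, val, aro, press, motion, 1)
  colnames(X) <- c("mean", "VAL", "ARO", "press", colnames(motion), "constant")
  roles <- c("task", "parametric", "parametric", "press", rep("motion", 6),
             "constant")
  d <- new_design_matrix(X, roles, tr_s, n_volumes, bins, hrf, notes)
  d$non_estimable <- setdiff(d$non_estimable, "constant")
  if (length(notes)) warning(paste(notes, collapse = "; "), call. = FALSE)
  d
}

# --- discrete-cosine high-pass ----------------------------------------------

#' Discrete-cosine high-pass basis
#'
#' Orthonormal DCT drift basis for a run of `n` volumes. The basis contains
#' every cosine with frequency at or below `cutoff_hz` plus two guard
#' components just above it, so that a drift at exactly the cutoff period is
#' removed rather than left straddling the band edge.
#'
#' @param n Number of volumes.
#' @param tr_s Repetition time (s).
#' @param cutoff_hz High-pass cutoff frequency (default 1/128 Hz).
#' @return An `n x K` matrix with orthonormal columns (constant excluded).
#' @export
dct_basis <- function(n, tr_s, cutoff_hz = 1 / 128) {
  if (cutoff_hz >= 1 / (2 * tr_s)) {
    abort_argument("high-pass cutoff must lie below the Nyquist frequency")
  }
  K <- min(n - 1L, floor(2 * n * tr_s * cutoff_hz) + 2L)
  t <- seq_len(n)
  D <- vapply(seq_len(K),
              function(k) sqrt(2 / n) * cos(pi * (2 * t - 1) * k / (2 * n)),
              numeric(n))
  colnames(D) <- paste0("dct", seq_len(K))
  D
}

#' Remove low-frequency drift by DCT projection
#'
#' Regresses the discrete-cosine drift basis (see [dct_basis()]) out of a
#' series, a matrix of series, a [parcel_ts()], or a design matrix. The same
#' residual-forming projection must be applied to data and design before
#' fitting; [fit_glm()] enforces this. The constant column of a design is
#' unaffected (the basis is orthogonal to it).
#'
#' @param x Numeric vector/matrix, `parcel_ts`, or `design_matrix`.
#' @param tr_s Repetition time; taken from the object when it carries one.
#' @param cutoff_hz Cutoff frequency in Hz (default 1/128).
#' @return Object of the same type, filtered.
#' @export
dct_highpass <- function(x, tr_s = NULL, cutoff_hz = 1 / 128) {
  UseMethod("dct_highpass")
}

#' @export
dct_highpass.default <- function(x, tr_s = NULL, cutoff_hz = 1 / 128) {
  if (is.null(tr_s)) abort_argument("`tr_s` is required for plain series")
  v <- is.null(dim(x))
  X <- as.matrix(x)
  D <- dct_basis(nrow(X), tr_s, cutoff_hz)
  out <- X - D %*% crossprod(D, X)
  if (v) as.vector(out) else out
}

#' @export
dct_highpass.parcel_ts <- function(x, tr_s = NULL, cutoff_hz = 1 / 128) {
  x$data <- dct_highpass.default(x$data, tr_s %||% x$tr_s, cutoff_hz)
  attr(x, "highpass_cutoff_hz") <- cutoff_hz
  x
}

#' @export
dct_highpass.design_matrix <- function(x, tr_s = NULL, cutoff_hz = 1 / 128) {
  keep <- x$column_roles != "constant"
  D <- dct_basis(x$n_volumes, tr_s %||% x$tr_s, cutoff_hz)
  x$matrix[, keep] <- x$matrix[, keep, drop = FALSE] -
    D %*% crossprod(D, x$matrix[, keep, drop = FALSE])
  x$highpass <- list(applied = TRUE, cutoff_hz = cutoff_hz)
  x
}
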