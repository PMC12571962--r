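# Psychophysiological interactions: seed eigenvariate extraction, hemodynamic
# deconvolution on a discrete-cosine basis, PPI regressor construction and the
# PPI GLM yielding per-parcel connectivity-modulation estimates.

#' First eigenvariate of a seed parcel
#'
#' Extracts the first left singular vector of the centred `time x voxel`
#' matrix of the seed parcel, sign-aligned to correlate positively with the
#' parcel-mean signal and rescaled to the mean voxel standard deviation.
#'
#' @param ts A [parcel_ts()] (high-pass filter the data first).
#' @param seed_id Parcel id of the seed.
#' @return An object of class `seed_signal` with `eigenvariate`,
#'   `explained_variance`, `parcel_id` and `tr_s`.
#' @export
extract_eigenvariate <- function(ts, seed_id) {
  stopifnot(inherits(ts, "parcel_ts"))
  cols <- which(ts$voxel_map$parcel_id == seed_id)
  if (!length(cols)) abort_argument(sprintf("parcel %s not present", seed_id))
  Y <- ts$data[, cols, drop = FALSE]
  Yc <- sweep(Y, 2L, colMeans(Y))
  sds <- apply(Yc, 2L, stats::sd)
  if (all(sds == 0)) abort_validation("seed parcel has zero variance")
  sv <- svd(Yc, nu = 1L, nv = 0L)
  u <- sv$u[, 1L]
  if (stats::sd(rowMeans(Yc)) > 0 &&
      stats::cor(u, rowMeans(Yc)) < 0) u <- -u
  ev <- u / stats::sd(u) * mean(sds)
  structure(
    list(parcel_id = seed_id, eigenvariate = ev,
         explained_variance = sv$d[1L]^2 / sum(sv$d^2), tr_s = ts$tr_s),
    class = "seed_signal"
  )
}

#' @export
print.seed_signal <- function(x, ...) {
  cat(sprintf("<seed_signal> parcel %s, %d volumes, explained variance %.2f\n",
              x$parcel_id, length(x$eigenvariate), x$explained_variance))
  invisible(x)
}

# cache of deconvolution operators keyed by (n_volumes, bins, tr, hrf hash)
.deconv_cache <- new.env(parent = emptyenv())

# microtime DCT basis, its HRF-convolved downsampled image A, and crossprod
deconv_operator <- function(n_volumes, tr_s, bins, hrf) {
  key <- paste(n_volumes, tr_s, bins, hrf$dt_s,
               signif(sum(hrf$values * seq_along(hrf$values)), 12), sep = "|")
  if (!is.null(.deconv_cache[[key]])) return(.deconv_cache[[key]])
  n_micro <- micro_length(n_volumes, bins)
  dt <- tr_s / bins
  # frequencies up to the volume-level Nyquist: k / (2 * n_micro * dt) <= 1/(2 tr)
  Kd <- n_volumes
  t <- seq_len(n_micro)
  D <- vapply(seq_len(Kd),
              function(k) sqrt(2 / n_micro) * cos(pi * (2 * t - 1) * k / (2 * n_micro)),
              numeric(n_micro))
  freqs <- seq_len(Kd) / (2 * n_micro * dt)
  # convolve every basis column with the HRF, sample at volume times
  nfft <- stats::nextn(n_micro + length(hrf$values) - 1L, 2L)
  hf <- stats::fft(c(hrf$values, numeric(nfft - length(hrf$values))))
  Dp <- rbind(D, matrix(0, nfft - n_micro, Kd))
  conv <- Re(stats::mvfft(stats::mvfft(Dp) * hf, inverse = TRUE)) / nfft
  A <- conv[micro_sample_index(n_volumes, bins), , drop = FALSE]
  # -3 dB frequency of the HRF magnitude response
  H <- Mod(hf)[seq_len(nfft %/% 2)]
  f_axis <- (seq_len(nfft %/% 2) - 1) / (nfft * dt)
  f3db <- f_axis[which(H <= H[1] / sqrt(2))[1]]
  AtA <- crossprod(A)
  d3 <- diag(AtA)[which.min(abs(freqs - f3db))]
  op <- list(D = D, A = A, AtA = AtA, freqs = freqs, f3db = f3db,
             diag_f3db = d3)
  .deconv_cache[[key]] <- op
  op
}

#' Deconvolve a BOLD series to a microtime neural estimate
#'
#' Estimates the underlying neural series of an observed BOLD signal by ridge
#' regression on a discrete-cosine basis: the neural series is expanded in
#' low-frequency cosines, each basis function is convolved with the HRF and
#' sampled at volume times, and the coefficients minimise the residual sum of
#' squares plus a frequency-weighted ridge penalty that suppresses components
#' the HRF cannot distinguish from noise.
#'
#' @param seed_signal A `seed_signal` (or a plain numeric series with `tr_s`
#'   supplied).
#' @param hrf HRF kernel at microtime resolution; defaults to
#'   [canonical_hrf()] at `tr_s / bins`.
#' @param lambda Ridge weight. The default scales the penalty so that a
#'   component at the HRF's -3 dB frequency is shrunk by 5%.
#' @param bins Microtime bins per TR.
#' @param tr_s Repetition time, required when `seed_signal` is a bare vector.
#' @return Numeric microtime series of length `n_volumes * bins` with
#'   attributes `dt_s` and `lambda`.
#' @export
deconvolve_bold <- function(seed_signal, hrf = NULL, lambda = NULL,
                            bins = 16L, tr_s = NULL) {
  if (inherits(seed_signal, "seed_signal")) {
    y <- seed_signal$eigenvariate
    tr_s <- seed_signal$tr_s
  } else {
    y <- as.numeric(seed_signal)
    if (is.null(tr_s)) abort_argument("`tr_s` is required for a bare series")
  }
  n_volumes <- length(y)
  dt <- tr_s / bins
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  if (abs(hrf$dt_s - dt) > 1e-9) {
    abort_argument("`hrf` must be sampled at tr_s / bins")
  }
  op <- deconv_operator(n_volumes, tr_s, bins, hrf)
  # penalty grows quadratically in frequency relative to the HRF -3 dB point;
  # the default weight shrinks a component at that frequency by 5%
  pen <- (op$freqs / op$f3db)^2
  if (is.null(lambda)) {
    lambda <- op$diag_f3db * 0.05 / 0.95
  }
  yc <- y - mean(y)
  M <- op$AtA + lambda * diag(pen)
  co <- tryCatch(solve(M, crossprod(op$A, yc)), error = function(e) {
    warning("deconvolution system singular; penalty increased", call. = FALSE)
    solve(M + 10 * lambda * diag(ncol(M)), crossprod(op$A, yc))
  })
  z <- as.vector(op$D %*% co)
  attr(z, "dt_s") <- dt
  attr(z, "lambda") <- lambda
  z
}

# psychological microtime vector: +1 in `pos` category epochs, -1 in `neg`
psych_vector <- function(events, pos, neg, n_micro, dt) {
  for (cc in c(pos, neg)) {
    if (!any(events$category == cc)) {
      abort_argument(sprintf("category %s absent from events", cc))
    }
  }
  ep <- events[events$category == pos, ]
  en <- events[events$category == neg, ]
  neural_boxcar(ep$onset_s, ep$picture_duration_s, n_micro, dt) -
    neural_boxcar(en$onset_s, en$picture_duration_s, n_micro, dt)
}

#' PPI design matrix
#'
#' Builds the connectivity model: the three category task regressors, the
#' observed seed eigenvariate, two psychophysiological-interaction regressors
#' (NEG-NEU and POS-NEU) formed by multiplying the deconvolved neural seed
#' estimate with the +1/-1 psychological vector at microtime and reconvolving
#' with the HRF, plus press, motion and constant columns (14 columns in
#' total).
#'
#' @inheritParams build_model1_design
#' @param seed_signal A `seed_signal` from [extract_eigenvariate()].
#' @param lambda Deconvolution ridge weight (see [deconvolve_bold()]).
#' @return A `design_matrix` with additional roles `seed` and `ppi`.
#' @export
build_ppi_design <- function(events, seed_signal, motion = NULL, n_volumes,
                             tr_s, hrf = NULL, bins = 16L, lambda = NULL) {
  events <- event_table(events)
  stopifnot(inherits(seed_signal, "seed_signal"))
  if (length(seed_signal$eigenvariate) != n_volumes) {
    abort_validation("seed signal length must equal n_volumes")
  }
  motion <- check_motion(motion, n_volumes)
  dt <- tr_s / bins
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  n_micro <- micro_length(n_volumes, bins)

  base <- build_model1_design(events, motion, n_volumes, tr_s, hrf, bins)
  z <- deconvolve_bold(seed_signal, hrf, lambda = lambda, bins = bins)
  ppi <- vapply(list(`PPI_NEG-NEU` = c("NEG", "NEU"),
                     `PPI_POS-NEU` = c("POS", "NEU")),
                function(pair) {
                  p <- psych_vector(events, pair[1], pair[2], n_micro, dt)
                  convolve_regressor(z * p, hrf, n_volumes, bins)
                }, numeric(n_volumes))
  X <- cbind(base$matrix[, c("NEG", "NEU", "POS"), drop = FALSE],
             seed = seed_signal$eigenvariate, ppi,
             base$matrix[, c("press", paste0("motion", 1:6), "constant")])
  colnames(X) <- c("NEG", "NEU", "POS", "seed", "PPI_NEG-NEU", "PPI_POS-NEU",
                   "press", paste0("motion", 1:6), "constant")
  roles <- c(rep("task", 3), "seed", rep("ppi", 2), "press", rep("motion", 6),
             "constant")
  d <- new_design_matrix(X, roles, tr_s, n_volumes, bins, hrf, base$notes)
  d$non_estimable <- setdiff(d$non_estimable, "constant")
  attr(d, "seed_id") <- seed_signal$parcel_id
  d
}

#' Estimate connectivity-modulation contrasts from a PPI design
#'
#' Fits the PPI GLM with the same AR(1) ReML engine as [fit_glm()] (applying
#' the high-pass to the design first if needed) and returns the per-voxel
#' beta of a PPI column, by default the NEG-NEU connectivity modulation. The
#' seed parcel is excluded from the targets.
#'
#' @param design A `design_matrix` from [build_ppi_design()].
#' @param ts A [parcel_ts()].
#' @param column PPI column whose beta is reported
#'   (default `"PPI_NEG-NEU"`).
#' @param cutoff_hz High-pass cutoff applied when the design is not yet
#'   filtered.
#' @return A `contrast_result` tibble (`parcel_id`, `voxel`, `value`) with the
#'   seed id in attribute `"seed_id"`.
#' @export
estimate_fc_contrasts <- function(design, ts, column = "PPI_NEG-NEU",
                                  cutoff_hz = 1 / 128) {
  stopifnot(inherits(design, "design_matrix"))
  if (!column %in% design$column_names || design$column_roles[match(column, design$column_names)] != "ppi") {
    abort_argument(sprintf("`%s` is not a ppi column of this design", column))
  }
  if (!isTRUE(design$highpass$applied)) {
    design <- dct_highpass(design, cutoff_hz = cutoff_hz)
  }
  fit <- fit_glm(design, ts)
  out <- compute_contrast(fit, stats::setNames(1, column), name = column)
  seed_id <- attr(design, "seed_id")
  if (!is.null(seed_id)) {
    out <- out[out$parcel_id != seed_id, ]
    attr(out, "seed_id") <- seed_id
  }
  out
}
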