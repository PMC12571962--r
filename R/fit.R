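# GLM estimation: AR(1) restricted-maximum-likelihood noise modelling with
# prewhitened (generalised least squares) parameter estimates.

# AR(1) whitening transform scaled so that W %*% R %*% t(W) = I for the AR(1)
# correlation matrix R: first row kept, later rows (y_t - rho*y_{t-1})/sqrt(1-rho^2).
ar1_whiten <- function(X, rho) {
  if (rho == 0) return(X)
  X <- as.matrix(X)
  n <- nrow(X)
  rbind(X[1L, , drop = FALSE],
        (X[-1L, , drop = FALSE] - rho * X[-n, , drop = FALSE]) / sqrt(1 - rho^2))
}

#' Fit the GLM with AR(1) ReML prewhitening
#'
#' Estimates, for every parcel, an AR(1) residual-correlation coefficient by
#' restricted maximum likelihood (profiling the voxel variances, pooling the
#' REML criterion over the parcel's voxels), prewhitens data and design with
#' the estimated coefficient, and computes generalised-least-squares betas per
#' voxel. The AR coefficient is maximised over a grid (step 0.02) which keeps
#' the whitened-design factorisations shared across parcels.
#'
#' @param design A `design_matrix` with the high-pass filter already applied
#'   (see [dct_highpass()]); the same projection is applied to the data here.
#' @param ts A [parcel_ts()] of the same run.
#' @param rho_grid Candidate AR(1) coefficients (must lie in (-1, 1)).
#' @return A `glm_fit` object with elements `betas` (K x voxels), `sigma2`,
#'   `rho` (per parcel), `effective_df`, `design` and `voxel_map`.
#' @export
fit_glm <- function(design, ts, rho_grid = seq(-0.4, 0.9, by = 0.02)) {
  stopifnot(inherits(design, "design_matrix"), inherits(ts, "parcel_ts"))
  if (!isTRUE(design$highpass$applied)) {
    abort_argument("apply `dct_highpass()` to the design before fitting")
  }
  if (any(abs(rho_grid) >= 1)) abort_argument("`rho_grid` must lie in (-1, 1)")
  X <- design$matrix
  n <- nrow(X); K <- ncol(X)
  if (ts$n_volumes != n) abort_validation("data and design disagree on n_volumes")
  if (n <= K + 10L) abort_argument("need n_volumes > K + 10 for stable fits")

  # apply the identical residual-forming projection to the data
  Y <- dct_highpass.default(ts$data, design$tr_s, design$highpass$cutoff_hz)
  # ...but retain the signal mean so the constant stays estimable
  Y <- sweep(Y, 2L, colMeans(ts$data), `+`)

  n_hp <- ncol(dct_basis(n, design$tr_s, design$highpass$cutoff_hz))
  p_eff <- K
  rank_deficient <- FALSE

  map <- ts$voxel_map
  parcels <- unique(map$parcel_id)
  parcel_of <- match(map$parcel_id, parcels)
  n_parcel <- length(parcels)

  # REML profile over the rho grid, pooled over each parcel's voxels
  reml <- matrix(-Inf, n_parcel, length(rho_grid))
  for (j in seq_along(rho_grid)) {
    rho <- rho_grid[j]
    Xw <- ar1_whiten(X, rho)
    qrX <- qr(Xw)
    if (j == 1L && qrX$rank < K) rank_deficient <- TRUE
    ldXX <- 2 * sum(log(abs(diag(qr.R(qrX))[seq_len(qrX$rank)])))
    Yw <- ar1_whiten(Y, rho)
    Qty <- qr.qty(qrX, Yw)[seq_len(qrX$rank), , drop = FALSE]
    rss <- pmax(colSums(Yw^2) - colSums(Qty^2), 1e-300)
    ldR <- (n - 1) * log(1 - rho^2)
    # per-voxel REML criterion with sigma^2 profiled out, summed within parcel
    crit_v <- -(n - p_eff) * log(rss / (n - p_eff))
    sums <- as.vector(rowsum(crit_v, parcel_of))
    nv <- as.vector(rowsum(rep(1, length(crit_v)), parcel_of))
    reml[, j] <- 0.5 * (sums - nv * (ldXX + ldR))
  }
  best <- apply(reml, 1L, which.max)
  rho_hat <- rho_grid[best]

  betas <- matrix(NA_real_, K, ncol(Y),
                  dimnames = list(design$column_names, colnames(Y)))
  sigma2 <- numeric(ncol(Y))
  for (g in unique(best)) {
    rho <- rho_grid[g]
    cols <- which(best[parcel_of] == g)
    Xw <- ar1_whiten(X, rho)
    Yw <- ar1_whiten(Y[, cols, drop = FALSE], rho)
    if (rank_deficient) {
      sv <- svd(Xw)
      pos <- sv$d > max(sv$d) * 1e-10
      bh <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], Yw)) / sv$d[pos])
    } else {
      bh <- qr.coef(qr(Xw), Yw)
    }
    res <- Yw - Xw %*% bh
    betas[, cols] <- bh
    sigma2[cols] <- colSums(res^2) / (n - p_eff)
  }
  if (rank_deficient) {
    warning("design is rank deficient; betas computed via pseudo-inverse",
            call. = FALSE)
  }
  structure(
    list(betas = betas, sigma2 = sigma2,
         rho = stats::setNames(rho_hat, parcels),
         effective_df = n - p_eff - n_hp,
         design = design, voxel_map = map, method = "reml_grid"),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d columns x %d voxels (%d parcels); median rho = %.2f, effective df = %d\n",
              nrow(x$betas), ncol(x$betas), length(x$rho),
              stats::median(x$rho), x$effective_df))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.glm_fit <- function(x, ...) {
  tibble::tibble(
    parcel_id = rep(x$voxel_map$parcel_id, each = nrow(x$betas)),
    voxel = rep(x$voxel_map$voxel, each = nrow(x$betas)),
    term = rep(rownames(x$betas), times = ncol(x$betas)),
    estimate = as.vector(x$betas)
  )
}

#' @exportS3Method generics::glance
glance.glm_fit <- function(x, ...) {
  tibble::tibble(
    n_voxels = ncol(x$betas), n_parcels = length(x$rho),
    median_rho = stats::median(x$rho),
    median_sigma2 = stats::median(x$sigma2),
    effective_df = x$effective_df
  )
}

#' Contrast weights by name
#'
#' Builds a full-length weight vector for a design from a compact
#' specification such as `"NEG - NEU"` or a named numeric vector.
#'
#' @param design A `design_matrix`.
#' @param contrast Either a character expression over column names using `+`
#'   and `-` (e.g. `"NEG - NEU"`, `"VAL"`), or a named numeric vector.
#' @return A named numeric vector of length `ncol(design$matrix)`.
#' @export
contrast_weights <- function(design, contrast) {
  w <- stats::setNames(numeric(length(design$column_names)),
                       design$column_names)
  if (is.character(contrast)) {
    stopifnot(length(contrast) == 1L)
    toks <- strsplit(gsub(" ", "", contrast), "(?=[+-])", perl = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    sign <- 1
    for (tk in toks) {
      if (tk == "+") { sign <- 1; next }
      if (tk == "-") { sign <- -1; next }
      nm <- sub("^[+-]", "", tk)
      s <- if (startsWith(tk, "-")) -1 else sign
      if (!nm %in% names(w)) abort_argument(paste0("unknown column: ", nm))
      w[nm] <- w[nm] + s
      sign <- 1
    }
  } else {
    if (is.null(names(contrast))) {
      if (length(contrast) != length(w)) {
        abort_argument("unnamed weights must cover every design column")
      }
      w[] <- contrast
    } else {
      bad <- setdiff(names(contrast), names(w))
      if (length(bad)) abort_argument(paste0("unknown column(s): ",
                                             paste(bad, collapse = ", ")))
      w[names(contrast)] <- contrast
    }
  }
  w
}

#' Linear contrast of GLM betas
#'
#' Computes a weighted sum of the fitted betas for every voxel. Weights that
#' touch a non-estimable (all-zero) design column raise an error.
#'
#' @param fit A `glm_fit`.
#' @param weights Contrast specification passed to [contrast_weights()], or a
#'   numeric vector of length K.
#' @param name Optional label stored with the result.
#' @return A tibble of class `contrast_result` with columns `parcel_id`,
#'   `voxel`, `value`.
#' @export
compute_contrast <- function(fit, weights, name = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  w <- contrast_weights(fit$design, weights)
  touched <- names(w)[w != 0]
  bad <- intersect(touched, fit$design$non_estimable)
  if (length(bad)) {
    abort_argument(paste0("contrast touches non-estimable column(s): ",
                          paste(bad, collapse = ", ")))
  }
  value <- as.vector(crossprod(fit$betas, w))
  out <- tibble::tibble(parcel_id = fit$voxel_map$parcel_id,
                        voxel = fit$voxel_map$voxel,
                        value = value)
  attr(out, "weights") <- w
  attr(out, "name") <- name %||% paste(deparse(weights), collapse = "")
  class(out) <- c("contrast_result", class(out))
  out
}
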