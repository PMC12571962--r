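# Inclusion Bayes factors for the repeated-measures ANCOVA: marginal
# likelihoods of a g-prior linear mixed model estimated by Monte Carlo over
# the variance-scale mixture, combined by Bayesian model averaging.

# orthonormal sum-to-zero contrast matrix for a factor with `a` levels
orthonormal_contrasts <- function(a) {
  H <- stats::contr.helmert(a)
  sweep(H, 2L, sqrt(colSums(H^2)), `/`)
}

expand_factor <- function(f) {
  f <- factor(f)
  Q <- orthonormal_contrasts(nlevels(f))
  X <- Q[as.integer(f), , drop = FALSE]
  colnames(X) <- paste0(levels(f)[-1], "_c")
  X
}

# shared closed-form: log p(y | g) up to a model-independent constant, for a
# linear model with flat intercept, Jeffreys sigma^2 and beta ~ N(0, sigma^2 G)
log_marginal_given_g <- function(XtX, Xty, yty, n, g_cols) {
  sg <- sqrt(g_cols)
  S <- XtX * tcrossprod(sg)
  diag(S) <- diag(S) + 1
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  u <- sg * Xty
  v <- backsolve(R, u, transpose = TRUE)
  quad <- max(yty - sum(v^2), 1e-300)
  -sum(log(diag(R))) - (n - 1) / 2 * log(quad)
}

#' Inclusion Bayes factors for a repeated-measures ANCOVA
#'
#' Computes, for each predictor of interest (within-subject factor,
#' between-subject factor and their interaction), the inclusion Bayes factor
#' `BF_incl` -- the ratio of posterior to prior inclusion odds across a model
#' space -- via Bayesian model averaging. The model space is the null model
#' (intercept, nuisance covariates and a subject term) plus every admissible
#' model respecting marginality (the interaction only enters together with
#' both main effects); all models have equal prior probability.
#'
#' Effects carry zero-centred scaled priors in the Jeffreys-Zellner-Siow
#' style: each effect class has its own relative scale `g` with
#' `g ~ InverseGamma(1/2, r^2/2)`, i.e. a Cauchy(0, r) scale on standardised
#' effects. Factors are coded with orthonormal sum-to-zero contrasts and
#' continuous covariates are standardised. Conditional on the `g` vector the
#' marginal likelihood is closed form (flat intercept, Jeffreys `sigma^2`);
#' the remaining low-dimensional mixture over `g` is integrated by Monte
#' Carlo with `mcmc_passes` draws shared across models, and a split-half
#' consistency check flags unstable estimates.
#'
#' @param data Long-format data frame, one row per subject and within-factor
#'   level.
#' @param response,subject,within,between Column names (strings). `within`
#'   and/or `between` may be `NULL`.
#' @param covariates Character vector of nuisance covariate columns included
#'   in every model.
#' @param r_fixed Cauchy scale for the factors of interest
#'   (default sqrt(2)/2).
#' @param r_random Cauchy scale for the subject term (default 1).
#' @param r_cov Cauchy scale for covariate slopes (default sqrt(2)/4).
#' @param mcmc_passes Monte-Carlo draws for the g-mixture (default 5000).
#' @param seed Optional integer seed making the draws reproducible.
#' @param matched_models If `TRUE`, inclusion odds for each effect are formed
#'   only over matched model pairs (models differing in that effect alone);
#'   the default averages across all models.
#' @return An object of class `bf_inclusion`: tibbles `inclusion`
#'   (per-predictor `log10_bf_incl` with Monte-Carlo error) and `models`
#'   (prior/posterior probabilities), plus the draw settings.
#' @export
rmancova_inclusion_bf <- function(data, response, subject,
                                  within = NULL, between = NULL,
                                  covariates = character(),
                                  r_fixed = sqrt(2) / 2, r_random = 1,
                                  r_cov = sqrt(2) / 4,
                                  mcmc_passes = 5000, seed = NULL,
                                  matched_models = FALSE) {
  data <- as.data.frame(data)
  for (col in c(response, subject, within, between, covariates)) {
    if (!col %in% names(data)) abort_argument(paste0("column not found: ", col))
  }
  y <- data[[response]]
  if (any(!is.finite(y))) abort_validation("response contains missing values")
  n <- length(y)
  subj <- factor(data[[subject]])

  if (!is.null(within)) {
    wf <- factor(data[[within]])
    counts <- table(subj, wf)
    bad <- rownames(counts)[apply(counts, 1L, function(r) any(r != 1L))]
    if (length(bad)) {
      abort_validation(paste0("unbalanced within-subject cells for subject(s): ",
                              paste(bad, collapse = ", ")))
    }
  }

  # --- design blocks ---------------------------------------------------------
  blocks <- list()
  if (length(covariates)) {
    covX <- do.call(cbind, lapply(covariates, function(cv) {
      v <- data[[cv]]
      if (is.numeric(v)) {
        s <- stats::sd(v)
        if (s == 0) {
          warning(sprintf("covariate %s is constant; dropped", cv), call. = FALSE)
          return(NULL)
        }
        matrix((v - mean(v)) / s, ncol = 1,
               dimnames = list(NULL, cv))
      } else {
        X <- expand_factor(v)
        colnames(X) <- paste0(cv, seq_len(ncol(X)))
        X
      }
    }))
    if (!is.null(covX) && ncol(covX)) blocks$cov <- covX
  }
  multi_row_subjects <- !is.null(within)
  if (multi_row_subjects) blocks$subject <- expand_factor(subj)
  if (!is.null(within)) blocks$within <- expand_factor(data[[within]])
  if (!is.null(between)) blocks$between <- expand_factor(data[[between]])
  if (!is.null(within) && !is.null(between)) {
    W <- blocks$within; B <- blocks$between
    XI <- do.call(cbind, lapply(seq_len(ncol(B)), function(j) W * B[, j]))
    colnames(XI) <- paste0("ix", seq_len(ncol(XI)))
    blocks$interaction <- XI
  }
  r_of <- c(cov = r_cov, subject = r_random, within = r_fixed,
            between = r_fixed, interaction = r_fixed)

  base_classes <- intersect(c("cov", "subject"), names(blocks))
  interest <- intersect(c("within", "between", "interaction"), names(blocks))
  model_sets <- list(character(0))
  if ("within" %in% interest) model_sets <- c(model_sets, list("within"))
  if ("between" %in% interest) model_sets <- c(model_sets, list("between"))
  if (all(c("within", "between") %in% interest)) {
    model_sets <- c(model_sets, list(c("within", "between")),
                    list(c("within", "between", "interaction")))
  }

  yc <- y - mean(y)
  yty <- sum(yc^2)
  prep <- lapply(model_sets, function(set) {
    classes <- c(base_classes, set)
    X <- do.call(cbind, blocks[classes])
    X <- sweep(X, 2L, colMeans(X))
    cls <- rep(classes, vapply(blocks[classes], ncol, integer(1)))
    list(XtX = crossprod(X), Xty = as.vector(crossprod(X, yc)), cls = cls)
  })

  # shared g draws per effect class across all models
  all_classes <- unique(unlist(lapply(prep, `[[`, "cls")))
  draw <- function() {
    vapply(all_classes, function(cl) {
      1 / stats::rgamma(mcmc_passes, shape = 0.5, rate = r_of[[cl]]^2 / 2)
    }, numeric(mcmc_passes))
  }
  G <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(dim(G))) G <- matrix(G, ncol = length(all_classes))

  logm <- vapply(prep, function(pm) {
    idx <- match(pm$cls, all_classes)
    lw <- vapply(seq_len(mcmc_passes), function(i) {
      log_marginal_given_g(pm$XtX, pm$Xty, yty, n, G[i, idx])
    }, numeric(1))
    c(log_mean_exp(lw),
      abs(log_mean_exp(lw[seq_len(mcmc_passes %/% 2)]) -
          log_mean_exp(lw[(mcmc_passes %/% 2 + 1):mcmc_passes])),
      stats::sd(exp(lw - max(lw))) / mean(exp(lw - max(lw))) / sqrt(mcmc_passes))
  }, numeric(3))
  log_marg <- logm[1L, ]
  split_gap <- logm[2L, ]
  mc_se <- logm[3L, ]

  post <- exp(log_marg - log_sum_exp(log_marg))
  model_labels <- vapply(model_sets, function(s) {
    if (!length(s)) "null" else paste(s, collapse = "+")
  }, character(1))

  incl <- purrr::map_dfr(interest, function(eff) {
    has_eff <- vapply(model_sets, function(s) eff %in% s, logical(1))
    if (matched_models) {
      # matched pairs: models containing the effect but none of its
      # higher-order interactions, against the same models minus the effect
      has_ix <- vapply(model_sets, function(s) "interaction" %in% s, logical(1))
      with_eff <- has_eff & (eff == "interaction" | !has_ix)
      without <- vapply(model_sets, function(s) {
        any(vapply(model_sets[with_eff],
                   function(sw) setequal(sw, union(s, eff)), logical(1)))
      }, logical(1)) & !has_eff
    } else {
      with_eff <- has_eff
      without <- !has_eff
    }
    post_odds <- sum(post[with_eff]) / sum(post[without])
    prior_odds <- sum(with_eff) / sum(without)
    se <- sqrt(sum(mc_se[with_eff | without]^2)) / log(10)
    tibble::tibble(predictor = eff,
                   log10_bf_incl = log10(post_odds / prior_odds),
                   mc_error = se)
  })

  structure(
    list(inclusion = incl,
         models = tibble::tibble(model = model_labels,
                                 prior_prob = 1 / length(model_sets),
                                 post_prob = post,
                                 log_marginal = log_marg,
                                 mc_se = mc_se),
         mcmc_passes = mcmc_passes, seed = seed,
         converged = all(split_gap < 0.25),
         matched_models = matched_models),
    class = "bf_inclusion"
  )
}

#' @export
print.bf_inclusion <- function(x, ...) {
  cat(sprintf("<bf_inclusion> %d models, %d Monte-Carlo passes%s\n",
              nrow(x$models), x$mcmc_passes,
              if (x$converged) "" else " [convergence flag raised]"))
  df <- as.data.frame(x$inclusion)
  df$log10_bf_incl <- round(df$log10_bf_incl, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bf_inclusion <- function(x, ...) x$inclusion

#' @exportS3Method generics::glance
glance.bf_inclusion <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$models), mcmc_passes = x$mcmc_passes,
                 converged = x$converged,
                 best_model = x$models$model[which.max(x$models$post_prob)])
}
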