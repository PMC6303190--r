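#' Robust standardized regression (Tukey bisquare IRLS)
#'
#' Outcome and predictors are z-scored, then fitted by iteratively
#' reweighted least squares with Tukey bisquare weights (tuning constant
#' 4.685) via [MASS::rlm()], so the coefficients are standardized betas.
#' When no residual exceeds the bisquare tuning radius the fit coincides
#' with ordinary least squares.
#'
#' @param y Outcome vector.
#' @param X Predictor data frame or matrix (no intercept column).
#' @param tails `"two"` (default) or `"one"`; one-tailed p-values are
#'   halved when the estimated sign matches the declared direction and
#'   `1 - p/2` otherwise.
#' @param directions Named vector of expected signs (+1/-1) used when
#'   `tails = "one"`; predictors without a declared direction are tested
#'   two-tailed.
#' @return A `regression_result`: `coefficients` (term, beta, se, t, p),
#'   `n`, `k` (number of predictors), `rss`, `r2`, `bic`, `vif` (for >= 2
#'   predictors), and the fitted model.
#' @export
robust_regress <- function(y, X, tails = c("two", "one"),
                           directions = NULL) {
  tails <- match.arg(tails)
  X <- as.data.frame(X)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop("need n > number of predictors + 1")
  sds <- vapply(X, sd, numeric(1))
  if (any(sds == 0)) stop("constant predictor column: ",
                          paste(names(X)[sds == 0], collapse = ", "))
  Xz <- as.data.frame(scale(X))
  if (qr(as.matrix(Xz))$rank < k) stop("rank-deficient design")
  yz <- if (sd(y) == 0) rep(0, n) else scale(y)[, 1]
  dat <- cbind(.y = yz, Xz)
  fit <- MASS::rlm(.y ~ ., data = dat, psi = MASS::psi.bisquare,
                   c = 4.685, maxit = 100)
  sm <- summary(fit)$coefficients
  beta <- sm[-1, "Value"]
  se <- sm[-1, "Std. Error"]
  tval <- beta / se
  df <- n - k - 1
  p <- 2 * pt(-abs(tval), df)
  if (tails == "one") {
    dir_vec <- rep(NA_real_, k)
    names(dir_vec) <- names(Xz)
    if (!is.null(directions))
      dir_vec[names(directions)] <- directions
    one <- !is.na(dir_vec)
    match_sign <- sign(beta[one]) == sign(dir_vec[one])
    p[one] <- ifelse(match_sign, p[one] / 2, 1 - p[one] / 2)
  }
  # floor keeps BIC finite for (near-)perfect fits and degenerate outcomes
  rss <- max(sum(resid(fit)^2), 1e-12)
  tss <- sum((yz - mean(yz))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 0
  res <- structure(list(
    coefficients = data.frame(term = names(Xz), beta = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(p), stringsAsFactors = FALSE),
    n = n, k = k, rss = rss, r2 = r2,
    vif = if (k >= 2) vif(Xz) else NULL,
    model = fit), class = "regression_result")
  res$bic <- regression_bic(res)
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Robust regression: n = %d, R2 = %.3f, BIC = %.2f\n",
              x$n, x$r2, x$bic))
  co <- x$coefficients
  co$beta <- round(co$beta, 3); co$se <- round(co$se, 3)
  co$t <- round(co$t, 2); co$p <- signif(co$p, 3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from the OLS regression of predictor j on the
#' remaining predictors; values above 10 trigger a warning, perfect
#' collinearity yields `Inf` with a flag.
#'
#' @param X Predictor data frame or matrix with at least two columns.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("vif needs >= 2 predictors")
  out <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(X)
  if (any(!is.finite(out)))
    attr(out, "flag") <- "perfect_collinearity"
  if (any(out[is.finite(out)] > 10))
    warning("variance inflation factor above 10 for: ",
            paste(names(out)[out > 10], collapse = ", "))
  out
}

#' Partial R-squared of the predictors dropped from a nested model
#'
#' Difference in explained variance between a full model and a reduced
#' model whose predictors are a subset of the full model's.
#'
#' @param full,reduced `regression_result`s from [robust_regress()].
#' @export
partial_r2 <- function(full, reduced) {
  ft <- full$coefficients$term
  rt <- reduced$coefficients$term
  if (!all(rt %in% ft)) stop("reduced model is not nested in the full model")
  full$r2 - reduced$r2
}

#' Gaussian-likelihood BIC of a fitted regression
#'
#' `BIC = n * log(RSS / n) + k_total * log(n)` where `k_total` counts the
#' slope parameters, the intercept and the error variance. The convention
#' only matters up to an additive constant shared by models on the same
#' data, so BIC differences are internally consistent.
#'
#' @param result A `regression_result`, or a list with `n`, `rss`, `k`.
#' @export
regression_bic <- function(result) {
  n <- result$n; rss <- result$rss; k <- result$k
  if (is.null(n) || is.null(rss) || is.null(k)) stop("need n, rss and k")
  if (rss <= 0) stop("RSS must be positive")
  n * log(rss / n) + (k + 2) * log(n)
}

#' Label a bivariate relation as linear or quadratic by BIC
#'
#' Fits `y ~ x`, `y ~ x^2` and `y ~ x + x^2` by [robust_regress()] and
#' returns the BIC-minimizing structure. When the two-term model wins, the
#' label follows the term with the larger absolute standardized beta.
#'
#' @param x Predictor; `y` outcome.
#' @param y Outcome vector.
#' @export
quad_vs_linear <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stop("need n >= 10")
  if (sd(x) == 0) stop("degenerate predictor")
  fits <- list(
    linear = robust_regress(y, data.frame(x = x)),
    quadratic = robust_regress(y, data.frame(x2 = x^2)),
    both = robust_regress(y, data.frame(x = x, x2 = x^2)))
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  structure_ <- names(which.min(bics))
  label <- structure_
  if (structure_ == "both") {
    co <- fits$both$coefficients
    label <- if (abs(co$beta[co$term == "x2"]) >
                   abs(co$beta[co$term == "x"])) "quadratic" else "linear"
  }
  list(label = label, structure = structure_, fit = fits[[structure_]],
       bic = bics)
}

#' Screen subjects against the data-quality exclusion rules
#'
#' Flags, with strict inequalities, subjects whose task performance
#' (proportion correct over non-missed task trials) is above 85% or below
#' 60%, who chose a single confidence rating more than 90% of the time
#' (missed trials excluded before the rating histogram), whose median
#' confidence response time is below 850 ms, or who missed more than 5% of
#' task trials. Any flagged subject is excluded from group analyses.
#'
#' @param trials Trial records for one or more subjects (task phases are
#'   screened; calibration rows are ignored).
#' @return An `exclusion_report`: per-subject flags, counts per reason and
#'   the retained subject ids.
#' @export
apply_exclusions <- function(trials) {
  task <- trials[trials$phase %in% c("task1", "task2"), , drop = FALSE]
  req <- c("subject_id", "d", "choice", "confidence", "confidence_rt_ms",
           "missed")
  miss <- setdiff(req, names(task))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  per <- lapply(split(task, task$subject_id), function(tr) {
    sc <- tr[!tr$missed & !is.na(tr$choice), , drop = FALSE]
    acc <- mean(sc$choice == sc$d)
    rated <- sc$confidence[!is.na(sc$confidence)]
    modal <- if (length(rated)) max(table(rated)) / length(rated) else NA
    med_rt <- median(sc$confidence_rt_ms, na.rm = TRUE)
    miss_frac <- mean(tr$missed)
    data.frame(subject_id = tr$subject_id[1],
               performance_out_of_range = acc > 0.85 || acc < 0.60,
               single_rating = !is.na(modal) && modal > 0.90,
               fast_confidence_rt = !is.na(med_rt) && med_rt < 850,
               missed_trials = miss_frac > 0.05)
  })
  flags <- do.call(rbind, per)
  rownames(flags) <- NULL
  flags$excluded <- flags$performance_out_of_range | flags$single_rating |
    flags$fast_confidence_rt | flags$missed_trials
  structure(list(
    flags = flags,
    counts = colSums(flags[, c("performance_out_of_range", "single_rating",
                               "fast_confidence_rt", "missed_trials",
                               "excluded")]),
    retained = flags$subject_id[!flags$excluded]),
    class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion screen:", nrow(x$flags), "subjects,",
      x$counts[["excluded"]], "excluded\n")
  print(x$counts)
  invisible(x)
}

#' BIC comparison of model variants as predictors of radicalism
#'
#' For each fitted variant, regresses composite radicalism on the
#' subject-level `mu_low` and `mu_high` estimates plus the variant's
#' weight parameter(s) (by [robust_regress()]), and additionally on the
#' single-weight reductions of the temporal and choice-weighting variants;
#' reports each regression's BIC relative to the set minimum (the best
#' model has a difference of zero).
#'
#' @param fits_by_variant Named list of fit lists (elements as returned by
#'   [fit_population()] or bare lists of `fit_result`s), e.g. for
#'   `temporal_weighting`, `choice_weighting`, `choice_bias`.
#' @param composite Composite radicalism scores aligned with the fitted
#'   subjects.
#' @return Data frame with `model`, `family`, `predictors`, `bic`,
#'   `delta_bic`, sorted by `delta_bic`.
#' @export
compare_models_radicalism <- function(fits_by_variant, composite) {
  get_fits <- function(x) if (!is.null(x$fits)) x$fits else x
  fits_by_variant <- lapply(fits_by_variant, get_fits)
  ids <- lapply(fits_by_variant, function(fl)
    vapply(fl, function(f) as.numeric(f$subject_id), numeric(1)))
  if (length(unique(lapply(ids, unname))) != 1L)
    stop("subject sets differ across variants")
  stopifnot(length(composite) == length(ids[[1]]))
  param_table <- function(fl, pars) {
    as.data.frame(lapply(setNames(pars, pars), function(p)
      vapply(fl, function(f) f$estimates[[p]], numeric(1))))
  }
  weight_sets <- list(
    choice_bias = list(full = "w_bias"),
    temporal_weighting = list(full = c("w_pre", "w_post"),
                              w_pre = "w_pre", w_post = "w_post"),
    choice_weighting = list(full = c("w_confirmatory", "w_disconfirmatory"),
                            w_confirmatory = "w_confirmatory",
                            w_disconfirmatory = "w_disconfirmatory"))
  rows <- list()
  for (variant in names(fits_by_variant)) {
    sets <- weight_sets[[variant]]
    if (is.null(sets)) next
    fl <- fits_by_variant[[variant]]
    for (set_name in names(sets)) {
      pars <- c("mu_low", "mu_high", sets[[set_name]])
      X <- param_table(fl, pars)
      fit <- robust_regress(composite, X)
      rows[[paste(variant, set_name, sep = ".")]] <- data.frame(
        model = if (set_name == "full") variant
                else paste(variant, set_name, sep = ":"),
        family = variant,
        predictors = paste(pars, collapse = "+"),
        bic = fit$bic, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab[order(tab$delta_bic), ]
}
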