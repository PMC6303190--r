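#' Outcome probabilities of the snapped (choice, rating) grid
#'
#' Quadrature probability of every joint outcome (action in `{-1, +1}`,
#' rating on the 9-point grid) for one trial type, including the clip-and-
#' snap report stage: the rating probability mass in each grid cell is the
#' Gaussian report-noise mass between the cell midpoint boundaries, with
#' the outer cells absorbing the clipped tails. Useful as an exact
#' reference for Monte-Carlo outcome frequencies; sums to 1 up to
#' quadrature truncation error.
#'
#' @param params A [subject_model_params()].
#' @param d True side, `+1` or `-1`.
#' @param post_level `"none"`, `"low"` or `"high"`.
#' @param n_nodes Quadrature nodes per dimension.
#' @return Data frame with `action`, `rating`, `prob`.
#' @export
outcome_probs <- function(params, d, post_level = "none", n_nodes = 121L) {
  stopifnot(d %in% c(-1, 1))
  s <- params$strengths
  sig <- params$sigma_report
  grid <- .rating_grid
  edges <- c(-Inf, grid[-length(grid)] + 0.0625, Inf)
  rating_mass <- function(conf) {
    # conf: vector; returns matrix [length(conf) x 9]
    if (sig == 0) {
      idx <- findInterval(conf, edges[-c(1, length(edges))]) + 1L
      outer(idx, seq_along(grid), "==") * 1
    } else {
      hi <- outer(conf, edges[-1], function(cf, e) pnorm(e, cf, sig))
      lo <- outer(conf, edges[-length(edges)],
                  function(cf, e) pnorm(e, cf, sig))
      hi - lo
    }
  }
  moments <- if (post_level != "none") mixture_moments(s)
             else list(mu = s$mu_low, sigma2 = 1)
  span <- 8
  out <- expand.grid(action = c(-1, 1), rating = grid)
  out$prob <- 0
  for (a in c(-1, 1)) {
    lo <- if (a > 0) max(params$m, -s$mu_low - span) else -s$mu_low - span
    hi <- if (a > 0) s$mu_low + span else min(params$m, s$mu_low + span)
    if (hi <= lo) next
    h <- (hi - lo) / n_nodes
    x <- lo + (seq_len(n_nodes) - 0.5) * h
    w_x <- dnorm(x, d * s$mu_low) * h
    if (post_level == "none") {
      conf <- .confidence_vec(x, rep(NA_real_, length(x)), a,
                              params$variant_params, moments)
      probs <- colSums(w_x * rating_mass(conf))
    } else {
      theta_post <- if (post_level == "high") s$mu_high else s$mu_low
      hp <- (2 * (s$mu_high + span)) / n_nodes
      y <- -s$mu_high - span + (seq_len(n_nodes) - 0.5) * hp
      w_y <- dnorm(y, d * theta_post) * hp
      probs <- numeric(length(grid))
      for (i in seq_along(x)) {
        conf <- .confidence_vec(rep(x[i], length(y)), y, a,
                                params$variant_params, moments)
        probs <- probs + w_x[i] * colSums(w_y * rating_mass(conf))
      }
    }
    out$prob[out$action == a] <- probs
  }
  out
}

# simulate aggregate confidence from a parameter set: mean rating for
# correct and incorrect trials in each condition
.simulate_cells <- function(params, n_trials,
                            conditions = c("task1", "low", "high")) {
  s <- params$strengths
  res <- list()
  for (cond in conditions) {
    d <- sample(rep(c(-1, 1), length.out = n_trials))
    x_pre <- rnorm(n_trials, d * s$mu_low, 1)
    a <- decide(x_pre, params$m)
    if (cond == "task1") {
      x_post <- rep(NA_real_, n_trials)
      moments <- list(mu = s$mu_low, sigma2 = 1)
    } else {
      theta <- if (cond == "high") s$mu_high else s$mu_low
      x_post <- rnorm(n_trials, d * theta, 1)
      moments <- mixture_moments(s)
    }
    conf <- .confidence_vec(x_pre, x_post, a, params$variant_params, moments)
    rating <- simulate_report(conf, params$sigma_report)
    correct <- a == d
    res[[cond]] <- data.frame(
      condition = cond,
      accuracy_class = c("incorrect", "correct"),
      mean_confidence = c(mean(rating[!correct]), mean(rating[correct])))
  }
  do.call(rbind, res)
}

#' Posterior-predictive confidence table with a radical-decile split
#'
#' For each fitted subject, draws parameter settings from a Gaussian
#' approximation around the MAP (covariance from the inverse transformed-
#' scale Hessian; the point estimate is used when the Hessian is
#' unavailable or `n_draws = 1`), simulates `n_trials` per condition
#' (confidence task, low and high post-decision evidence) per draw, and
#' aggregates mean confidence for correct and incorrect trials. Subjects
#' are split into the `top_frac` most radical (by composite score) versus
#' the rest, and group means with 95% confidence intervals are returned
#' per cell.
#'
#' @param fits List of `fit_result`s (or the result of
#'   [fit_population()]).
#' @param composite Composite radicalism scores, one per fitted subject.
#' @param n_draws Parameter draws per subject (default 100).
#' @param n_trials Simulated trials per condition per draw (default 4000).
#' @param top_frac Fraction labelled radical (default 0.1).
#' @return Data frame: `group`, `condition`, `accuracy_class`,
#'   `mean_confidence`, `ci_lo`, `ci_hi`, `n_subjects`.
#' @export
posterior_predictive <- function(fits, composite, n_draws = 100L,
                                 n_trials = 4000L, top_frac = 0.1) {
  if (!is.null(fits$fits)) fits <- fits$fits
  if (n_draws < 1L || n_trials < 1L)
    stop("n_draws and n_trials must be >= 1")
  n <- length(fits)
  stopifnot(length(composite) == n)
  n_radical <- max(1L, round(top_frac * n))
  radical <- rank(-composite, ties.method = "first") <= n_radical
  subj_cells <- vector("list", n)
  for (j in seq_len(n)) {
    f <- fits[[j]]
    draw_pars <- matrix(rep(f$par, n_draws), nrow = n_draws, byrow = TRUE)
    if (n_draws > 1L && !is.null(f$hessian)) {
      cov <- tryCatch(solve(f$hessian + diag(1e-6, nrow(f$hessian))),
                      error = function(e) NULL)
      if (!is.null(cov)) {
        ev <- eigen(cov, symmetric = TRUE)
        ev$values <- pmax(ev$values, 0)
        L <- ev$vectors %*% diag(sqrt(ev$values), nrow(cov))
        draw_pars <- draw_pars +
          matrix(rnorm(n_draws * nrow(cov)), n_draws) %*% t(L)
      }
    }
    acc <- NULL
    for (k in seq_len(n_draws)) {
      p <- .unpack_par(draw_pars[k, ], f$variant)
      vp <- switch(f$variant,
        base = variant_params("base"),
        temporal_weighting = variant_params("temporal_weighting",
                                            w_pre = p$w1, w_post = p$w2),
        choice_weighting = variant_params("choice_weighting",
                                          w_confirmatory = p$w1,
                                          w_disconfirmatory = p$w2),
        choice_bias = variant_params("choice_bias",
                                     w_bias = min(max(p$w1, 1e-4), 1 - 1e-4)))
      sp <- subject_model_params(m = p$m,
                                 strengths = evidence_strengths(
                                   max(p$mu_low, 1e-4),
                                   max(p$mu_high, p$mu_low, 1e-4)),
                                 sigma_report = p$sigma_report,
                                 variant_params = vp)
      cells <- .simulate_cells(sp, n_trials)
      acc <- if (is.null(acc)) cells$mean_confidence
             else acc + cells$mean_confidence
    }
    cells$mean_confidence <- acc / n_draws
    cells$subject <- j
    subj_cells[[j]] <- cells
  }
  all_cells <- do.call(rbind, subj_cells)
  all_cells$group <- ifelse(radical[all_cells$subject], "radical",
                            "moderate")
  agg <- aggregate(mean_confidence ~ group + condition + accuracy_class,
                   data = all_cells, FUN = function(v)
                     c(mean = mean(v), se = sd(v) / sqrt(length(v)),
                       n = length(v)))
  out <- data.frame(group = agg$group, condition = agg$condition,
                    accuracy_class = agg$accuracy_class,
                    mean_confidence = agg$mean_confidence[, "mean"],
                    ci_lo = agg$mean_confidence[, "mean"] -
                      1.96 * agg$mean_confidence[, "se"],
                    ci_hi = agg$mean_confidence[, "mean"] +
                      1.96 * agg$mean_confidence[, "se"],
                    n_subjects = agg$mean_confidence[, "n"])
  out
}
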