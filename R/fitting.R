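#' Prior specification for model fitting
#'
#' Group-level priors of the fitting model: the decision criterion is drawn
#' from `N(mu_m, sigma_m)`, report noise from a half-normal with scale
#' `sigma_report_scale`, variant weights from `N(w_mean, w_sd)` (choice
#' bias from `N(wbias_mean, wbias_sd)` on the probability scale), and the
#' internal evidence strengths are not fitted hierarchically but are
#' constrained by unit-SD normal priors centered on the subject's observed
#' d-prime over two at each stimulus strength.
#'
#' @param mu_m,sigma_m Criterion prior mean and SD.
#' @param sigma_report_scale Half-normal scale of the report-noise prior.
#' @param w_mean,w_sd Prior for temporal / choice-weighting weights.
#' @param wbias_mean,wbias_sd Prior for the choice-bias probability.
#' @param strength_sd SD of the evidence-strength priors.
#' @export
prior_spec <- function(mu_m = 0, sigma_m = 1, sigma_report_scale = 0.1,
                       w_mean = 1, w_sd = 1, wbias_mean = 0.5, wbias_sd = 1,
                       strength_sd = 1) {
  stopifnot(sigma_m > 0, sigma_report_scale > 0, w_sd > 0, wbias_sd > 0,
            strength_sd > 0)
  structure(list(mu_m = mu_m, sigma_m = sigma_m,
                 sigma_report_scale = sigma_report_scale,
                 w_mean = w_mean, w_sd = w_sd,
                 wbias_mean = wbias_mean, wbias_sd = wbias_sd,
                 strength_sd = strength_sd),
            class = "prior_spec")
}

#' Fitting configuration
#'
#' @param n_nodes_pre,n_nodes_post Midpoint-quadrature nodes per dimension
#'   (default 61; a minimum of 15 is enforced, below which the marginal
#'   likelihood is too coarse).
#' @param n_restarts Number of optimization starts (default 5): one
#'   informed start at the prior centers / observed type-1 statistics plus
#'   jittered restarts.
#' @param restart_sd SD of the jitter on transformed parameters.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param reltol Relative convergence tolerance of the objective.
#' @export
fit_config <- function(n_nodes_pre = 61L, n_nodes_post = 61L,
                       n_restarts = 5L, restart_sd = 0.5,
                       maxit = 500L, reltol = 1e-6) {
  if (n_nodes_pre < 15L || n_nodes_post < 15L)
    stop("quadrature grid too coarse: need at least 15 nodes per dimension")
  structure(list(n_nodes_pre = as.integer(n_nodes_pre),
                 n_nodes_post = as.integer(n_nodes_post),
                 n_restarts = as.integer(n_restarts),
                 restart_sd = restart_sd, maxit = as.integer(maxit),
                 reltol = reltol),
            class = "fit_config")
}

.variant_code <- function(variant) {
  switch(variant, base = 0L, temporal_weighting = 1L,
         choice_weighting = 2L, choice_bias = 3L,
         stop("unknown variant: ", variant))
}

# minimum allowed report-noise SD (numerical floor); the censored rating
# likelihood is well-posed as sigma -> 0, the floor only avoids degenerate
# 0/1 probit arguments
.sigma_report_floor <- 0.001

# probability that a noisy report around `conf` snaps to the grid cell of
# rating `r` (cell boundaries at +-0.0625; outer cells absorb clipped tails)
.cell_mass <- function(r, conf, sigma) {
  hi <- if (r > 1 - 1e-9) 1 else pnorm((r + 0.0625 - conf) / sigma)
  lo <- if (r < 1e-9) 0 else pnorm((r - 0.0625 - conf) / sigma)
  hi - lo
}

# aggregate rated task trials into unique (d, level, a, r) combos, sorted
# so the C++ kernel cache hits on consecutive rows
.aggregate_obs <- function(trials) {
  tr <- .scored_trials(trials, rated = TRUE)
  tr <- tr[tr$phase %in% c("task1", "task2"), , drop = FALSE]
  if (nrow(tr) == 0L) stop("no rated task trials to fit")
  tr$confidence <- snap_rating(tr$confidence)
  level <- match(tr$post_level, c("none", "low", "high")) - 1L
  agg <- aggregate(list(count = rep(1L, nrow(tr))),
                   by = list(d = tr$d, level = level, a = tr$choice,
                             r = tr$confidence), FUN = sum)
  agg[order(agg$a, agg$r), , drop = FALSE]
}

# observed d-prime at the two stimulus strengths: low from the two tasks,
# high from the high-strength calibration trials
.observed_dprimes <- function(trials) {
  task <- trials[trials$phase %in% c("task1", "task2"), , drop = FALSE]
  dlow <- dprime_criterion(task)
  cal_hi <- trials[trials$phase == "calibration" &
                     trials$stim_level == "high", , drop = FALSE]
  if (nrow(cal_hi) >= 10L) {
    dhigh <- dprime_criterion(cal_hi)$dprime
  } else {
    warning("no high-strength calibration trials; centering mu_high prior ",
            "at 1.5 x the low-strength d-prime")
    dhigh <- 1.5 * dlow$dprime
  }
  list(dlow = dlow$dprime, dhigh = dhigh, criterion = dlow$criterion)
}

# transformed parameter vector <-> natural parameters
.unpack_par <- function(par, variant) {
  p <- list(m = par[1],
            mu_low = exp(par[2]),
            mu_high = exp(par[2]) + exp(par[3]),
            sigma_report = .sigma_report_floor + exp(par[4]))
  w <- switch(variant,
    base = list(w1 = 0, w2 = 0),
    temporal_weighting = list(w1 = par[5], w2 = par[6]),
    choice_weighting = list(w1 = par[5], w2 = par[6]),
    choice_bias = list(w1 = plogis(par[5]), w2 = 0))
  c(p, w)
}

.log_prior <- function(p, variant, priors, dlow, dhigh) {
  lp <- dnorm(p$m, priors$mu_m, priors$sigma_m, log = TRUE) +
    dnorm(p$mu_low, dlow / 2, priors$strength_sd, log = TRUE) +
    dnorm(p$mu_high, dhigh / 2, priors$strength_sd, log = TRUE) +
    dnorm(p$sigma_report, 0, priors$sigma_report_scale, log = TRUE)
  lp + switch(variant,
    base = 0,
    temporal_weighting = dnorm(p$w1, priors$w_mean, priors$w_sd, log = TRUE) +
      dnorm(p$w2, priors$w_mean, priors$w_sd, log = TRUE),
    choice_weighting = dnorm(p$w1, priors$w_mean, priors$w_sd, log = TRUE) +
      dnorm(p$w2, priors$w_mean, priors$w_sd, log = TRUE),
    choice_bias = dnorm(p$w1, priors$wbias_mean, priors$wbias_sd, log = TRUE))
}

#' Quadrature log-likelihood of one observation (reference implementation)
#'
#' Marginalizes the latent internal sample(s) of a single `(d, post_level,
#' a, r)` observation by midpoint quadrature, in pure R. The choice enters
#' through the half-line of the pre-decision sample selected by the action
#' (the steep softmax treated as a step); the rating enters through the
#' Gaussian report-noise mass inside its snapped grid cell, the outer cells
#' absorbing the clipped tails. This mirrors the compiled likelihood used
#' by [fit_subject()] and exists as a readable reference and cross-check;
#' use [dataset_loglik()] for whole datasets.
#'
#' @param params A [subject_model_params()].
#' @param observation List with `d` (+-1), `post_level`, `a` (+-1), `r`
#'   (rating on `[0, 1]`).
#' @param n_nodes Nodes per quadrature dimension (minimum 15).
#' @return Log probability density of the observation.
#' @export
trial_loglik <- function(params, observation, n_nodes = 61L) {
  if (n_nodes < 15L) stop("quadrature grid too coarse")
  if (params$sigma_report <= 0) stop("sigma_report must be positive")
  stopifnot(observation$a %in% c(-1, 1), observation$d %in% c(-1, 1),
            observation$r >= 0, observation$r <= 1)
  p <- params
  s <- p$strengths
  vp <- p$variant_params
  d <- observation$d
  a <- observation$a
  r <- observation$r
  has_post <- observation$post_level != "none"
  moments <- if (has_post) mixture_moments(s)
             else list(mu = s$mu_low, sigma2 = 1)
  span <- 8
  lo <- if (a > 0) max(p$m, -s$mu_low - span) else -s$mu_low - span
  hi <- if (a > 0) s$mu_low + span else min(p$m, s$mu_low + span)
  if (hi <= lo) return(log(1e-300))
  h <- (hi - lo) / n_nodes
  x <- lo + (seq_len(n_nodes) - 0.5) * h
  w_x <- dnorm(x, d * s$mu_low) * h
  sig <- max(p$sigma_report, .sigma_report_floor)
  if (!has_post) {
    conf <- vapply(x, function(xi)
      combine_evidence(list(x_pre = xi, post_level = "none"), p, a,
                       moments)$confidence, numeric(1))
    mass <- vapply(conf, function(cf) .cell_mass(r, cf, sig), numeric(1))
    return(log(max(sum(w_x * mass), 1e-300)))
  }
  theta_post <- if (observation$post_level == "high") s$mu_high else s$mu_low
  plo <- -s$mu_high - span
  phi <- s$mu_high + span
  hp <- (phi - plo) / n_nodes
  y <- plo + (seq_len(n_nodes) - 0.5) * hp
  w_y <- dnorm(y, d * theta_post) * hp
  total <- 0
  for (i in seq_along(x)) {
    conf <- vapply(y, function(yj)
      combine_evidence(list(x_pre = x[i], x_post = yj, post_level =
                              observation$post_level), p, a,
                       moments)$confidence, numeric(1))
    mass <- vapply(conf, function(cf) .cell_mass(r, cf, sig), numeric(1))
    total <- total + w_x[i] * sum(w_y * mass)
  }
  log(max(total, 1e-300))
}

#' Quadrature log-likelihood of a subject's task data (compiled path)
#'
#' @param trials Trial records (task phases; calibration rows are ignored).
#' @param params A [subject_model_params()].
#' @param config A [fit_config()] (node counts are taken from it).
#' @return Total log-likelihood over non-missed rated task trials.
#' @export
dataset_loglik <- function(trials, params, config = fit_config()) {
  obs <- .aggregate_obs(trials)
  vp <- params$variant_params
  code <- .variant_code(vp$variant)
  w1 <- switch(vp$variant, base = 0, temporal_weighting = vp$w_pre,
               choice_weighting = vp$w_confirmatory,
               choice_bias = vp$w_bias)
  w2 <- switch(vp$variant, base = 0, temporal_weighting = vp$w_post,
               choice_weighting = vp$w_disconfirmatory, choice_bias = 0)
  cpp_loglik(as.integer(obs$d), as.integer(obs$level), as.integer(obs$a),
             obs$r, obs$count, params$m, params$strengths$mu_low,
             params$strengths$mu_high, max(params$sigma_report,
                                           .sigma_report_floor),
             code, w1, w2, config$n_nodes_pre, config$n_nodes_post)
}

#' Fit one model variant to a subject's choices and confidence ratings
#'
#' Maximum a posteriori estimation under the priors of [prior_spec()]: the
#' quadrature marginal likelihood of all rated task-1 and task-2 trials
#' plus the log priors is maximized by Nelder-Mead over the transformed
#' parameters (criterion; log evidence strengths with `mu_high >= mu_low`
#' enforced; log report noise above a 0.01 floor; variant weights, the
#' choice-bias weight on the logit scale). Multi-start: one informed start
#' (observed type-1 criterion and d-prime-based strengths, prior-mean
#' weights) plus jittered restarts.
#'
#' @param trials One subject's trial records (calibration rows supply the
#'   high-strength d-prime constraint).
#' @param variant Model variant name.
#' @param priors A [prior_spec()].
#' @param config A [fit_config()].
#' @return A `fit_result`: point estimates, log joint at the optimum,
#'   convergence diagnostics and the transformed-scale Hessian for
#'   posterior-predictive draws.
#' @export
fit_subject <- function(trials, variant = c("choice_bias", "base",
                                            "temporal_weighting",
                                            "choice_weighting"),
                        priors = prior_spec(), config = fit_config()) {
  variant <- match.arg(variant)
  if (is.null(trials) || nrow(trials) == 0L) stop("empty dataset")
  obs <- .aggregate_obs(trials)
  dp <- .observed_dprimes(trials)
  code <- .variant_code(variant)
  di <- as.integer(obs$d); li <- as.integer(obs$level)
  ai <- as.integer(obs$a); ri <- obs$r; ci <- obs$count
  negpost <- function(par) {
    p <- .unpack_par(par, variant)
    ll <- cpp_loglik(di, li, ai, ri, ci, p$m, p$mu_low, p$mu_high,
                     p$sigma_report, code, p$w1, p$w2,
                     config$n_nodes_pre, config$n_nodes_post)
    lp <- .log_prior(p, variant, priors, dp$dlow, dp$dhigh)
    v <- -(ll + lp)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(dp$criterion,
             log(max(dp$dlow / 2, 0.05)),
             log(max((dp$dhigh - dp$dlow) / 2, 0.05)),
             log(max(0.05 - .sigma_report_floor, 1e-3)))
  start <- switch(variant,
    base = start,
    temporal_weighting = c(start, priors$w_mean, priors$w_mean),
    choice_weighting = c(start, priors$w_mean, priors$w_mean),
    choice_bias = c(start, qlogis(min(max(priors$wbias_mean, 0.05), 0.95))))
  best <- NULL
  for (k in seq_len(max(1L, config$n_restarts))) {
    s0 <- if (k == 1L) start else
      start + rnorm(length(start), 0, config$restart_sd)
    o <- optim(s0, negpost, method = "Nelder-Mead",
               control = list(maxit = config$maxit,
                              reltol = config$reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: a fresh simplex from the optimum; convergence is declared when
  # it improves the objective by less than 0.01 log-units
  polish <- optim(best$par, negpost, method = "Nelder-Mead",
                  control = list(maxit = config$maxit,
                                 reltol = config$reltol))
  converged <- polish$value >= best$value - 0.01
  if (polish$value < best$value) best <- polish
  est <- .unpack_par(best$par, variant)
  estimates <- list(m = est$m, mu_low = est$mu_low, mu_high = est$mu_high,
                    sigma_report = est$sigma_report)
  estimates <- c(estimates, switch(variant,
    base = list(),
    temporal_weighting = list(w_pre = est$w1, w_post = est$w2),
    choice_weighting = list(w_confirmatory = est$w1,
                            w_disconfirmatory = est$w2),
    choice_bias = list(w_bias = est$w1)))
  hess <- tryCatch(optimHess(best$par, negpost), error = function(e) NULL)
  structure(list(subject_id = trials$subject_id[1], variant = variant,
                 estimates = estimates, log_joint = -best$value,
                 par = best$par, hessian = hess,
                 converged = converged,
                 flag = if (!converged) "non_convergence" else "ok",
                 dprime_low = dp$dlow, dprime_high = dp$dhigh),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit (", x$variant, "), subject ", x$subject_id, "\n", sep = "")
  est <- unlist(x$estimates)
  cat("  ", paste(sprintf("%s = %.3f", names(est), est), collapse = ", "),
      "\n  log joint = ", sprintf("%.2f", x$log_joint),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  invisible(x)
}

#' Fit a model variant to every subject of a population
#'
#' Default mode fits each subject independently under the supplied priors.
#' Hierarchical mode iterates empirical-Bayes updates: after each pass the
#' group means and SDs of the criterion and the variant weights are set to
#' the mean and SD of the subject estimates (SDs floored at 0.05) and the
#' subjects are refitted, until group means change by less than `tol`.
#'
#' @param population A `population` or a trial data frame with
#'   `subject_id`.
#' @param variant Model variant.
#' @param hierarchical Logical; default `FALSE`.
#' @param priors,config See [prior_spec()], [fit_config()].
#' @param tol,max_iter Hierarchical fixed-point controls.
#' @return List with `fits` (one `fit_result` per subject) and `priors`
#'   (the final, possibly updated, prior spec).
#' @export
fit_population <- function(population, variant = "choice_bias",
                           hierarchical = FALSE, priors = prior_spec(),
                           config = fit_config(), tol = 0.02,
                           max_iter = 3L) {
  trials <- if (inherits(population, "population")) population$trials
            else population
  by_subject <- split(trials, trials$subject_id)
  if (length(by_subject) < 2L && hierarchical) {
    warning("hierarchical mode needs >= 2 subjects; fitting independently")
    hierarchical <- FALSE
  }
  run_pass <- function(pr) lapply(by_subject, fit_subject, variant = variant,
                                  priors = pr, config = config)
  fits <- run_pass(priors)
  if (hierarchical) {
    for (it in seq_len(max_iter)) {
      ms <- vapply(fits, function(f) f$estimates$m, numeric(1))
      new <- priors
      new$mu_m <- mean(ms)
      new$sigma_m <- max(sd(ms), 0.05)
      if (variant %in% c("temporal_weighting", "choice_weighting")) {
        ws <- vapply(fits, function(f)
          unlist(f$estimates[setdiff(names(f$estimates),
                                     c("m", "mu_low", "mu_high",
                                       "sigma_report"))]), numeric(2))
        new$w_mean <- mean(ws)
        new$w_sd <- max(sd(ws), 0.05)
      } else if (variant == "choice_bias") {
        wb <- vapply(fits, function(f) f$estimates$w_bias, numeric(1))
        new$wbias_mean <- mean(wb)
        new$wbias_sd <- max(sd(wb), 0.05)
      }
      delta <- abs(new$mu_m - priors$mu_m)
      priors <- new
      fits <- run_pass(priors)
      if (delta < tol) break
    }
  }
  list(fits = fits, priors = priors)
}
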