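#' @useDynLib pdeconf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm dnorm pnorm qnorm runif rlnorm optim
#'   lm coef resid median sd cor quantile plogis qlogis complete.cases
#'   setNames aggregate nlminb pt optimHess
NULL

# 9-point confidence rating grid on the [0, 1] probability scale
.rating_grid <- seq(0, 1, by = 0.125)

# confidence is clamped away from 0/1 before report noise so that
# log-odds round-trips stay finite
.conf_eps <- 1e-6

#' Internal evidence strengths for the two stimulus levels
#'
#' Bundles the internal evidence strengths (in units of the internal-noise
#' standard deviation) for the weak (`mu_low`) and strong (`mu_high`)
#' stimulus conditions. Pre-decision evidence is always presented at the low
#' strength; post-decision evidence at either level.
#'
#' @param mu_low Internal evidence strength of the weak condition; positive.
#' @param mu_high Internal evidence strength of the strong condition; must be
#'   at least `mu_low`.
#' @return An object of class `evidence_strengths`.
#' @export
evidence_strengths <- function(mu_low, mu_high) {
  stopifnot(is.numeric(mu_low), is.numeric(mu_high),
            length(mu_low) == 1L, length(mu_high) == 1L)
  if (!is.finite(mu_low) || !is.finite(mu_high))
    stop("evidence strengths must be finite")
  if (mu_low <= 0) stop("mu_low must be positive")
  if (mu_high < mu_low) stop("mu_high must be >= mu_low")
  structure(list(mu_low = mu_low, mu_high = mu_high),
            class = "evidence_strengths")
}

#' Single-Gaussian moments of the evidence-strength mixture
#'
#' An observer who does not know which of the two evidence strengths was
#' presented treats an internal sample as drawn from an equal mixture of
#' `N(d * mu_low, 1)` and `N(d * mu_high, 1)` and approximates that mixture
#' by a single Gaussian. The mean is the average of the two strengths and
#' the variance follows from the law of total variance: the between-strength
#' spread plus the unit within-strength variance.
#'
#' @param strengths An [evidence_strengths()] pair.
#' @return List with components `mu` and `sigma2`.
#' @export
mixture_moments <- function(strengths) {
  if (!inherits(strengths, "evidence_strengths"))
    strengths <- evidence_strengths(strengths[[1]], strengths[[2]])
  mu <- (strengths$mu_low + strengths$mu_high) / 2
  sigma2 <- ((strengths$mu_high - strengths$mu_low) / 2)^2 + 1
  list(mu = mu, sigma2 = sigma2)
}

#' Log posterior odds of the rightward direction
#'
#' Under flat priors the log posterior odds that the rightward side held the
#' higher dot density equals the Gaussian log likelihood ratio of the
#' internal sample, which reduces to `2 * mu * x / sigma2`.
#'
#' @param x Internal sample(s); vectorized.
#' @param moments List with `mu` and `sigma2` as from [mixture_moments()].
#' @return Log-odds (natural log), same length as `x`.
#' @export
lo_direction <- function(x, moments) {
  if (moments$sigma2 <= 0) stop("sigma2 must be positive")
  2 * moments$mu * x / moments$sigma2
}

#' Log odds of being correct given the chosen action
#'
#' Conditions direction log-odds on the action: belief in "right" counts as
#' belief in "correct" only if the subject chose right.
#'
#' @param lo_dir Direction log-odds; vectorized.
#' @param action Choice, `+1` (right) or `-1` (left); scalar or vector.
#' @export
lo_correct <- function(lo_dir, action) {
  if (!all(action %in% c(-1, 1))) stop("action must be -1 or +1")
  action * lo_dir
}

#' Parameters of a post-decision integration model variant
#'
#' `base` is the Bayesian observer that sums pre- and post-decision log-odds.
#' `temporal_weighting` weights the two epochs by `w_pre`/`w_post`.
#' `choice_weighting` weights post-decision evidence by `w_confirmatory`
#' when it supports the chosen side and `w_disconfirmatory` otherwise.
#' `choice_bias` adds a fixed amount of subjective probability `w_bias` to
#' the chosen option (on the direction log-odds, before conditioning on the
#' action), and so also shifts confidence in the task without post-decision
#' evidence.
#'
#' @param variant One of `"base"`, `"temporal_weighting"`,
#'   `"choice_weighting"`, `"choice_bias"`.
#' @param w_pre,w_post Temporal weights (unitless).
#' @param w_confirmatory,w_disconfirmatory Choice-weighting weights.
#' @param w_bias Choice-bias probability in (0, 1).
#' @export
variant_params <- function(variant = c("base", "temporal_weighting",
                                       "choice_weighting", "choice_bias"),
                           w_pre = NULL, w_post = NULL,
                           w_confirmatory = NULL, w_disconfirmatory = NULL,
                           w_bias = NULL) {
  variant <- match.arg(variant)
  vp <- switch(variant,
    base = list(),
    temporal_weighting = {
      stopifnot(is.numeric(w_pre), is.numeric(w_post))
      list(w_pre = w_pre, w_post = w_post)
    },
    choice_weighting = {
      stopifnot(is.numeric(w_confirmatory), is.numeric(w_disconfirmatory))
      list(w_confirmatory = w_confirmatory,
           w_disconfirmatory = w_disconfirmatory)
    },
    choice_bias = {
      stopifnot(is.numeric(w_bias))
      if (w_bias <= 0 || w_bias >= 1) stop("w_bias must lie in (0, 1)")
      list(w_bias = w_bias)
    })
  structure(c(list(variant = variant), vp), class = "variant_params")
}

#' Full generative parameter set for one subject
#'
#' @param m Decision criterion in internal-noise SD units; the subject
#'   chooses right when the pre-decision sample exceeds `m`, which absorbs
#'   stimulus-independent response biases.
#' @param strengths An [evidence_strengths()] pair.
#' @param sigma_report Report-noise SD on the confidence-probability scale;
#'   positive (0 allowed for noiseless simulation).
#' @param variant_params A [variant_params()] object.
#' @export
subject_model_params <- function(m = 0,
                                 strengths = evidence_strengths(0.55, 0.85),
                                 sigma_report = 0.05,
                                 variant_params = pdeconf::variant_params("base")) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (!inherits(strengths, "evidence_strengths"))
    stop("strengths must be an evidence_strengths object")
  if (!is.numeric(sigma_report) || sigma_report < 0)
    stop("sigma_report must be >= 0")
  structure(list(m = m, strengths = strengths, sigma_report = sigma_report,
                 variant_params = variant_params),
            class = "subject_model_params")
}

#' @export
print.subject_model_params <- function(x, ...) {
  vp <- x$variant_params
  ws <- vp[setdiff(names(vp), "variant")]
  cat("Subject model parameters (", vp$variant, ")\n", sep = "")
  cat(sprintf("  m = %.3f, mu_low = %.3f, mu_high = %.3f, sigma_report = %.3f\n",
              x$m, x$strengths$mu_low, x$strengths$mu_high, x$sigma_report))
  if (length(ws))
    cat("  ", paste(sprintf("%s = %.3f", names(ws), unlist(ws)),
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Logistic mapping from log-odds correct to confidence
#'
#' @param lo Log-odds; vectorized.
#' @param eps Clamp distance from exact 0/1 (default `1e-6`), keeping
#'   subsequent log-odds transforms finite.
#' @export
confidence_from_logodds <- function(lo, eps = .conf_eps) {
  pmin(pmax(plogis(lo), eps), 1 - eps)
}

#' Combine pre- and post-decision evidence into confidence
#'
#' Computes the components of the confidence computation for one trial. All
#' variants first map internal samples to direction log-odds under the
#' observer's assumed likelihood `moments`, then condition on the action.
#' The additive variants (`base`, `temporal_weighting`, `choice_weighting`)
#' combine the action-conditioned components with their weights; the
#' `choice_bias` variant adds its bias term (sign set by the action) to the
#' summed direction log-odds *before* conditioning on the action, so that
#' the bias always favours the chosen option, with or without post-decision
#' evidence.
#'
#' @param sample List with `x_pre`, optional `x_post`, and `post_level`
#'   (`"none"`, `"low"` or `"high"`).
#' @param params A [subject_model_params()] object.
#' @param action Choice, `+1` or `-1`.
#' @param moments Assumed likelihood moments (list with `mu`, `sigma2`); in
#'   the task without post-decision evidence this is
#'   `list(mu = mu_low, sigma2 = 1)`, with post-decision evidence the
#'   agnostic [mixture_moments()] of the strength pair, applied to both
#'   samples.
#' @return List of class `confidence_computation` with `lo_dir_pre`,
#'   `lo_dir_post`, `lo_bias`, `lo_correct_total` and `confidence`.
#' @export
combine_evidence <- function(sample, params, action, moments) {
  if (!action %in% c(-1, 1)) stop("action must be -1 or +1")
  has_post <- !is.null(sample$post_level) && sample$post_level != "none"
  if (has_post && is.null(sample$x_post))
    stop("x_post required when post_level != 'none'")
  lo_pre <- lo_direction(sample$x_pre, moments)
  lo_post <- if (has_post) lo_direction(sample$x_post, moments) else 0
  vp <- params$variant_params
  lo_bias <- 0
  lo_total <- switch(vp$variant,
    base = action * lo_pre + action * lo_post,
    temporal_weighting =
      vp$w_pre * action * lo_pre + vp$w_post * action * lo_post,
    choice_weighting = {
      w <- if (!has_post) 0
           else if (sign(sample$x_post) == sign(action)) vp$w_confirmatory
           else vp$w_disconfirmatory
      action * lo_pre + w * action * lo_post
    },
    choice_bias = {
      lo_bias <- action * qlogis(vp$w_bias)
      action * (lo_pre + lo_post + lo_bias)
    })
  structure(list(lo_dir_pre = lo_pre, lo_dir_post = lo_post,
                 lo_bias = lo_bias, lo_correct_total = lo_total,
                 confidence = confidence_from_logodds(lo_total)),
            class = "confidence_computation")
}

# Vectorized confidence for simulation: x_post may contain NA for rows
# without post-decision evidence. `moments` as in combine_evidence.
.confidence_vec <- function(x_pre, x_post, action, vp, moments) {
  lo_pre <- lo_direction(x_pre, moments)
  lo_post <- lo_direction(ifelse(is.na(x_post), 0, x_post), moments)
  lo_total <- switch(vp$variant,
    base = action * (lo_pre + lo_post),
    temporal_weighting = vp$w_pre * action * lo_pre +
      vp$w_post * action * lo_post,
    choice_weighting = {
      w <- ifelse(is.na(x_post), 0,
                  ifelse(sign(x_post) == sign(action),
                         vp$w_confirmatory, vp$w_disconfirmatory))
      action * lo_pre + w * action * lo_post
    },
    choice_bias = action * (lo_pre + lo_post) + qlogis(vp$w_bias))
  confidence_from_logodds(lo_total)
}

#' Perceptual decision rule
#'
#' The fitting likelihood treats the choice as a steep softmax of the
#' pre-decision sample relative to the criterion (`slope` 1000 by default),
#' which is numerically a step function; simulation therefore defaults to
#' the deterministic rule `sign(x_pre - m)`. A tie at `x_pre == m` is broken
#' by a fair coin.
#'
#' @param x_pre Pre-decision internal sample(s).
#' @param m Decision criterion.
#' @param slope Softmax slope (> 0), used when `deterministic = FALSE`.
#' @param deterministic Use the step rule (default) or sample from the
#'   softmax.
#' @return Action(s) in `{-1, +1}`.
#' @export
decide <- function(x_pre, m, slope = 1000, deterministic = TRUE) {
  if (slope <= 0) stop("slope must be positive")
  if (deterministic) {
    a <- sign(x_pre - m)
    ties <- a == 0
    if (any(ties)) a[ties] <- ifelse(runif(sum(ties)) < 0.5, 1, -1)
    a
  } else {
    p <- plogis(slope * (x_pre - m))
    ifelse(runif(length(x_pre)) < p, 1, -1)
  }
}

#' Simulate a confidence report on the 9-point rating grid
#'
#' Adds Gaussian report noise to model confidence, clips to `[0, 1]` and
#' snaps to the nearest of the nine grid points `0, 0.125, ..., 1`.
#'
#' @param confidence Model confidence in (0, 1); vectorized.
#' @param sigma_report Report-noise SD (>= 0).
#' @export
simulate_report <- function(confidence, sigma_report) {
  if (sigma_report < 0) stop("sigma_report must be >= 0")
  r <- confidence + rnorm(length(confidence), 0, sigma_report)
  snap_rating(pmin(pmax(r, 0), 1))
}

#' Snap values on `[0, 1]` to the 9-point rating grid
#' @param r Numeric vector in `[0, 1]`.
#' @export
snap_rating <- function(r) {
  .rating_grid[pmax(1L, pmin(9L, round(r / 0.125) + 1L))]
}
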