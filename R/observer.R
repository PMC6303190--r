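# constrained shuffle: no more than max_run consecutive trials of one
# level; long runs are broken by swapping their last element with a
# randomly chosen element of the other level (repair converges for any n,
# where plain rejection sampling would not)
.interleave_levels <- function(levels, max_run = 4L) {
  s <- sample(levels)
  repeat {
    r <- rle(s)
    if (max(r$lengths) <= max_run) return(s)
    ends <- cumsum(r$lengths)
    for (i in which(r$lengths > max_run)) {
      pos <- ends[i]
      j <- sample(which(s != s[pos]), 1)
      tmp <- s[pos]; s[pos] <- s[j]; s[j] <- tmp
    }
  }
}

# shared trial engine for the two confidence tasks; post_level is a
# character vector per trial ("none", "low", "high")
.simulate_confidence_trials <- function(observer, post_level,
                                        low_log_strength, high_log_strength,
                                        phase) {
  n <- length(post_level)
  p <- observer$params
  theta_low <- psychometric_theta(low_log_strength, observer)
  theta_high <- psychometric_theta(high_log_strength, observer)
  d <- sample(rep(c(-1, 1), length.out = n))
  x_pre <- rnorm(n, d * theta_low, 1)
  theta_post <- ifelse(post_level == "high", theta_high, theta_low)
  x_post <- ifelse(post_level == "none", NA_real_,
                   rnorm(n, d * theta_post, 1))
  a <- decide(x_pre, p$m)
  # the subject's assumed likelihood: single strength in the task without
  # post-decision evidence, agnostic mixture when post-decision evidence
  # can occur
  any_post <- any(post_level != "none")
  moments <- if (any_post) mixture_moments(p$strengths)
             else list(mu = p$strengths$mu_low, sigma2 = 1)
  conf <- .confidence_vec(x_pre, x_post, a, p$variant_params, moments)
  conf <- pmin(pmax(conf, .conf_eps), 1 - .conf_eps)
  rating <- simulate_report(conf, p$sigma_report)
  if (isTRUE(observer$single_rating_collapse)) {
    fixed <- runif(n) < 0.95
    rating[fixed] <- 0.75
  }
  rt <- rlnorm(n, observer$rt_meanlog, observer$rt_sdlog)
  missed <- runif(n) < observer$miss_probability
  acc <- as.integer(a == d)
  choice <- a
  choice[missed] <- NA_integer_
  acc[missed] <- NA_integer_
  rating[missed] <- NA_real_
  rt[missed] <- NA_real_
  data.frame(phase = phase,
             trial = seq_len(n),
             d = d,
             log_strength_pre = low_log_strength,
             post_level = post_level,
             choice = choice,
             accuracy = acc,
             confidence = rating,
             confidence_rt_ms = rt,
             missed = missed,
             stim_level = "low",
             stringsAsFactors = FALSE)
}

#' Simulate the confidence task (task 1)
#'
#' 60 trials at the calibrated low stimulus strength, each a perceptual
#' choice followed by a 9-point confidence rating; no post-decision
#' evidence. If the observer's generating variant is `choice_bias`, the
#' bias term shifts these ratings too.
#'
#' @param observer An [observer_spec()] whose `params$strengths` reflect the
#'   calibrated strengths.
#' @param low_log_strength Converged low log dot difference.
#' @param n_trials Number of trials (default 60).
#' @return Data frame of trial records.
#' @export
simulate_task1 <- function(observer, low_log_strength, n_trials = 60L) {
  .simulate_confidence_trials(observer, rep("none", n_trials),
                              low_log_strength, low_log_strength, "task1")
}

#' Simulate the post-decision evidence integration task (task 2)
#'
#' 120 trials: the pre-decision stimulus is always at the low strength; a
#' post-decision stimulus whose physical direction always matches the true
#' side follows the choice, at the low strength on half the trials and the
#' high strength on the other half, pseudo-randomly interleaved (no more
#' than four consecutive trials of one level). The internal post-decision
#' sample can still land on either side of zero, so disconfirmatory
#' evidence arises from internal noise.
#'
#' @inheritParams simulate_task1
#' @param high_log_strength Stored high log dot difference (1.3 times the
#'   converged low value).
#' @param n_trials Total trials (default 120, split 60/60).
#' @export
simulate_task2 <- function(observer, low_log_strength, high_log_strength,
                           n_trials = 120L) {
  levels <- .interleave_levels(rep(c("low", "high"), length.out = n_trials))
  .simulate_confidence_trials(observer, levels, low_log_strength,
                              high_log_strength, "task2")
}

#' Simulate a complete session for one observer
#'
#' Runs calibration, sets the observer's internal evidence strengths from
#' the converged stimulus levels via the psychometric mapping, then
#' simulates the 60-trial confidence task and the 120-trial post-decision
#' evidence task.
#'
#' @param observer An [observer_spec()].
#' @param subject_id Identifier stamped on every trial row.
#' @param start_log_strength,step_size Staircase settings.
#' @return List with `trials` (300 rows), `calibration` (converged
#'   strengths and accuracies) and `observer` (with calibrated strengths).
#' @export
simulate_subject <- function(observer, subject_id = 1L,
                             start_log_strength = log(70), step_size = 0.1) {
  cal <- run_calibration(observer, start_log_strength, step_size)
  mu_low <- psychometric_theta(cal$low_log_strength, observer)
  mu_high <- psychometric_theta(cal$high_log_strength, observer)
  observer$params$strengths <- evidence_strengths(mu_low,
                                                  max(mu_high, mu_low))
  t1 <- simulate_task1(observer, cal$low_log_strength)
  t2 <- simulate_task2(observer, cal$low_log_strength,
                       cal$high_log_strength)
  trials <- rbind(cal$trials, t1, t2)
  trials <- cbind(subject_id = subject_id, trials)
  list(trials = trials, calibration = cal, observer = observer)
}
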