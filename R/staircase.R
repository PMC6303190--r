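# Stimulus geometry: a 625-cell grid in which the reference square fills
# 313 cells, so the dot difference can range from 1 to 312.
.ref_dots <- 313L
.max_dot_diff <- 312L
.log_bounds <- c(log(1), log(.max_dot_diff))

#' Create a 2-down-1-up staircase state
#'
#' The staircase operates on the natural logarithm of the dot difference:
#' two consecutive correct responses lower the stimulus strength by one
#' step, each error raises it by one step. Its accuracy asymptote is
#' `sqrt(0.5) ~ 70.7\%` correct.
#'
#' @param start_log_strength Initial log dot difference (default `log(70)`).
#' @param step_size Step in natural-log units (default 0.1).
#' @export
staircase_state <- function(start_log_strength = log(70), step_size = 0.1) {
  stopifnot(step_size > 0,
            start_log_strength >= .log_bounds[1],
            start_log_strength <= .log_bounds[2])
  structure(list(current_log_strength = start_log_strength,
                 consecutive_correct = 0L,
                 step_size = step_size,
                 trial_index = 0L,
                 history = numeric(0)),
            class = "staircase_state")
}

#' Advance a 2-down-1-up staircase by one trial
#'
#' @param state A [staircase_state()].
#' @param correct Logical; was the response correct?
#' @return Updated state; the presented strength is appended to `history`
#'   and the strength for the next trial is clipped to the stimulus bounds
#'   (`log(1)` to `log(312)`).
#' @export
staircase_step <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  state$history <- c(state$history, state$current_log_strength)
  state$trial_index <- state$trial_index + 1L
  if (!correct) {
    state$current_log_strength <- state$current_log_strength + state$step_size
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct == 0L) {
    state$consecutive_correct <- 1L
  } else {
    state$current_log_strength <- state$current_log_strength - state$step_size
    state$consecutive_correct <- 0L
  }
  state$current_log_strength <- min(max(state$current_log_strength,
                                        .log_bounds[1]), .log_bounds[2])
  state
}

#' Map physical stimulus strength to internal evidence strength
#'
#' Power-law psychometric mapping `theta = k * log_strength^gamma` from the
#' log dot difference to the internal evidence strength (in internal-noise
#' SD units). With the default exponent `gamma = 1.6`, multiplying the log
#' dot difference by 1.3 multiplies theta by `1.3^1.6 ~ 1.52`, which takes
#' an observer calibrated to ~71% correct to ~80% correct.
#'
#' @param log_strength Log dot difference (> 0).
#' @param observer An [observer_spec()].
#' @export
psychometric_theta <- function(log_strength, observer) {
  stopifnot(all(log_strength > 0))
  observer$k * log_strength^observer$gamma
}

#' Generative specification of a simulated observer
#'
#' @param k Psychometric gain (> 0): internal evidence strength per unit
#'   `log_strength^gamma`.
#' @param gamma Psychometric exponent (> 0); default 1.6.
#' @param params Generating [subject_model_params()]. The `strengths` slot
#'   is overwritten after calibration with the strengths implied by the
#'   converged stimulus levels.
#' @param rt_meanlog,rt_sdlog Lognormal confidence response-time
#'   distribution (ms); defaults give a median of 1500 ms.
#' @param miss_probability Per-trial probability of a lapse that blanks the
#'   choice and rating; in `[0, 1)`.
#' @param single_rating_collapse If `TRUE`, the observer reports its modal
#'   rating on almost every trial (a degenerate rater, used to exercise the
#'   exclusion screen).
#' @export
observer_spec <- function(k = 0.06, gamma = 1.6,
                          params = subject_model_params(),
                          rt_meanlog = log(1500), rt_sdlog = 0.4,
                          miss_probability = 0.01,
                          single_rating_collapse = FALSE) {
  stopifnot(k > 0, gamma > 0,
            miss_probability >= 0, miss_probability < 1)
  structure(list(k = k, gamma = gamma, params = params,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 miss_probability = miss_probability,
                 single_rating_collapse = single_rating_collapse),
            class = "observer_spec")
}

# one block of perceptual decisions (no confidence) at given log strengths
.simulate_choices <- function(observer, log_strengths, d) {
  theta <- psychometric_theta(log_strengths, observer)
  x_pre <- rnorm(length(d), d * theta, 1)
  a <- decide(x_pre, observer$params$m)
  list(x_pre = x_pre, choice = a, accuracy = as.integer(a == d))
}

#' Run the calibration phase for one observer
#'
#' Emulates a 120-trial calibration: 70 staircase trials (2-down-1-up on
#' the log dot difference) with 50 additional trials at 1.3 times the
#' current staircase log strength interleaved after 20 burn-in trials. The
#' converged low strength is the mean of the last 25 staircase log
#' strengths; the stored high strength is 1.3 times that value.
#'
#' @param observer An [observer_spec()].
#' @param start_log_strength,step_size Staircase settings; see
#'   [staircase_state()].
#' @return List with `low_log_strength`, `high_log_strength`, empirical
#'   accuracy at each (`acc_low` from the last 25 staircase trials,
#'   `acc_high` from the 50 high-strength trials) and the 120 calibration
#'   `trials` (a data frame in trial-record format).
#' @export
run_calibration <- function(observer, start_log_strength = log(70),
                            step_size = 0.1) {
  n_stair <- 70L
  n_high <- 50L
  st <- staircase_state(start_log_strength, step_size)
  # interleaving order: trials 1..20 staircase burn-in, then a shuffle of
  # the remaining 50 staircase and 50 high-strength trials
  kind <- c(rep("stair", 20L),
            sample(c(rep("stair", n_stair - 20L), rep("high", n_high))))
  n_tot <- length(kind)
  d <- sample(rep(c(-1, 1), length.out = n_tot))
  log_str <- numeric(n_tot)
  acc <- integer(n_tot)
  choice <- integer(n_tot)
  stair_acc <- integer(0)
  for (i in seq_len(n_tot)) {
    if (kind[i] == "stair") {
      ls <- st$current_log_strength
    } else {
      ls <- min(1.3 * st$current_log_strength, .log_bounds[2])
    }
    log_str[i] <- ls
    sim <- .simulate_choices(observer, ls, d[i])
    choice[i] <- sim$choice
    acc[i] <- sim$accuracy
    if (kind[i] == "stair") {
      st <- staircase_step(st, sim$accuracy == 1L)
      stair_acc <- c(stair_acc, sim$accuracy)
    }
  }
  at_bound <- st$history <= .log_bounds[1] + 1e-12 |
    st$history >= .log_bounds[2] - 1e-12
  if (mean(at_bound) > 0.5)
    warning("staircase pinned at a stimulus bound for more than half its trials")
  low <- mean(utils::tail(st$history, 25L))
  high <- min(1.3 * low, .log_bounds[2])
  trials <- data.frame(
    phase = "calibration",
    trial = seq_len(n_tot),
    d = d,
    log_strength_pre = log_str,
    post_level = "none",
    choice = choice,
    accuracy = acc,
    confidence = NA_real_,
    confidence_rt_ms = NA_real_,
    missed = FALSE,
    stim_level = ifelse(kind == "high", "high", "low"),
    stringsAsFactors = FALSE)
  list(low_log_strength = low,
       high_log_strength = high,
       acc_low = mean(utils::tail(stair_acc, 25L)),
       acc_high = mean(acc[kind == "high"]),
       trials = trials)
}
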