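# shared fixtures, all generated in code

cb_params <- function(w_bias = 0.65, m = 0, mu_low = 0.6, mu_high = 0.95,
                      sigma_report = 0.05) {
  subject_model_params(m = m,
                       strengths = evidence_strengths(mu_low, mu_high),
                       sigma_report = sigma_report,
                       variant_params = variant_params("choice_bias",
                                                       w_bias = w_bias))
}

base_params <- function(m = 0, mu_low = 0.6, mu_high = 0.95,
                        sigma_report = 0.05) {
  subject_model_params(m = m,
                       strengths = evidence_strengths(mu_low, mu_high),
                       sigma_report = sigma_report)
}

# task-format trial table simulated directly from model parameters (no
# calibration/psychometrics), with optional calibration rows for fitting
sim_task_trials <- function(params, n_task1 = 60L, n_task2 = 120L,
                            with_calibration = TRUE) {
  s <- params$strengths
  sim_block <- function(n, phase, levels) {
    d <- sample(rep(c(-1, 1), length.out = n))
    x_pre <- rnorm(n, d * s$mu_low, 1)
    a <- decide(x_pre, params$m)
    theta <- ifelse(levels == "high", s$mu_high,
                    ifelse(levels == "low", s$mu_low, NA))
    x_post <- ifelse(levels == "none", NA_real_, rnorm(n, d * theta, 1))
    moments <- if (any(levels != "none")) mixture_moments(s)
               else list(mu = s$mu_low, sigma2 = 1)
    conf <- pdeconf:::.confidence_vec(x_pre, x_post, a,
                                      params$variant_params, moments)
    data.frame(subject_id = 1L, phase = phase, trial = seq_len(n), d = d,
               log_strength_pre = 3.5, post_level = levels, choice = a,
               accuracy = as.integer(a == d),
               confidence = simulate_report(conf, params$sigma_report),
               confidence_rt_ms = 1500, missed = FALSE, stim_level = "low",
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    sim_block(n_task1, "task1", rep("none", n_task1)),
    sim_block(n_task2, "task2",
              sample(rep(c("low", "high"), length.out = n_task2))))
  if (with_calibration) {
    n_cal <- 50L
    d <- sample(rep(c(-1, 1), length.out = n_cal))
    x <- rnorm(n_cal, d * s$mu_high, 1)
    a <- decide(x, params$m)
    cal <- data.frame(subject_id = 1L, phase = "calibration",
                      trial = seq_len(n_cal), d = d, log_strength_pre = 4.5,
                      post_level = "none", choice = a,
                      accuracy = as.integer(a == d), confidence = NA_real_,
                      confidence_rt_ms = NA_real_, missed = FALSE,
                      stim_level = "high", stringsAsFactors = FALSE)
    out <- rbind(cal, out)
  }
  out
}

# one hand-built task trial row set with full control (for metric tests)
make_trials <- function(d, choice, confidence = NA_real_,
                        post_level = "none", phase = "task1",
                        rt = 1500, missed = FALSE) {
  n <- length(d)
  data.frame(subject_id = 1L, phase = phase, trial = seq_len(n), d = d,
             log_strength_pre = 3.5, post_level = post_level,
             choice = choice, accuracy = as.integer(choice == d),
             confidence = confidence, confidence_rt_ms = rt,
             missed = missed, stim_level = "low", stringsAsFactors = FALSE)
}

# planted 10-subject cohort: five clean subjects plus one violator of each
# exclusion rule (90% accuracy; 55% accuracy; 95% modal rating; 500 ms
# median RT; 8% missed trials)
make_exclusion_cohort <- function() {
  n <- 180L
  mk <- function(id, acc_rate, modal_share = 0.3, median_rt = 1500,
                 miss_frac = 0) {
    d <- rep(c(-1, 1), length.out = n)
    n_correct <- round(acc_rate * n)
    choice <- ifelse(seq_len(n) <= n_correct, d, -d)
    grid <- seq(0, 1, by = 0.125)
    n_modal <- round(modal_share * n)
    confidence <- c(rep(0.75, n_modal),
                    sample(grid[-7], n - n_modal, replace = TRUE))
    missed <- seq_len(n) > n * (1 - miss_frac)
    tr <- data.frame(subject_id = id, phase = "task1",
                     trial = seq_len(n), d = d,
                     log_strength_pre = 3.5, post_level = "none",
                     choice = choice, accuracy = as.integer(choice == d),
                     confidence = confidence,
                     confidence_rt_ms = median_rt, missed = missed,
                     stim_level = "low", stringsAsFactors = FALSE)
    tr$choice[tr$missed] <- NA_integer_
    tr$accuracy[tr$missed] <- NA_integer_
    tr$confidence[tr$missed] <- NA_real_
    tr
  }
  rbind(mk(1, 0.90),                      # performance above 85%
        mk(2, 0.55),                      # performance below 60%
        mk(3, 0.72, modal_share = 0.95),  # single rating > 90%
        mk(4, 0.72, median_rt = 500),     # fast confidence RTs
        mk(5, 0.72, miss_frac = 0.08),    # > 5% missed
        mk(6, 0.72), mk(7, 0.70), mk(8, 0.75), mk(9, 0.68), mk(10, 0.80))
}
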