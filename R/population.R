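#' Configuration of a synthetic population
#'
#' Defines the distributions of observer parameters and the planted
#' radicalism structure. Defaults reproduce the study conditions: a
#' quadratic relation of standardized strength 0.37 between political
#' orientation and dogmatic intolerance, a linear relation of 0.38 between
#' orientation and authoritarianism, a residual correlation of 0.21 between
#' the two radicalism facets, and a standardized coupling of 0.18 between
#' composite radicalism and the logit of the generating choice-bias weight.
#'
#' @param n_subjects Number of subjects (>= 2); default 400, the scale of
#'   the behavioral samples the generator emulates.
#' @param quad_coef Orientation -> dogmatic intolerance quadratic beta.
#' @param lin_coef Orientation -> authoritarianism linear beta.
#' @param factor_cor Residual dogmatism-authoritarianism correlation.
#' @param wbias_coupling Standardized coupling of logit(w_bias) to the
#'   composite radicalism score; 0 plants no association.
#' @param wbias_mean Population mean of the choice-bias weight (probability
#'   scale).
#' @param wbias_logit_sd SD of logit(w_bias) across subjects.
#' @param m_sd SD of the decision criterion across subjects.
#' @param k_meanlog,k_sdlog Lognormal distribution of the psychometric gain.
#' @param gamma Psychometric exponent (shared).
#' @param sigma_report Report-noise SD (shared).
#' @param miss_probability Per-trial lapse probability (shared).
#' @param rt_meanlog,rt_sdlog Confidence RT lognormal parameters (ms).
#' @param variant Generating model variant for every subject.
#' @export
population_config <- function(n_subjects = 400L,
                              quad_coef = 0.37,
                              lin_coef = 0.38,
                              factor_cor = 0.21,
                              wbias_coupling = 0.18,
                              wbias_mean = 0.55,
                              wbias_logit_sd = 0.5,
                              m_sd = 0.2,
                              k_meanlog = log(0.06),
                              k_sdlog = 0.15,
                              gamma = 1.6,
                              sigma_report = 0.05,
                              miss_probability = 0.01,
                              rt_meanlog = log(1500),
                              rt_sdlog = 0.4,
                              variant = "choice_bias") {
  stopifnot(n_subjects >= 2)
  cfg <- list(n_subjects = as.integer(n_subjects), quad_coef = quad_coef,
              lin_coef = lin_coef, factor_cor = factor_cor,
              wbias_coupling = wbias_coupling, wbias_mean = wbias_mean,
              wbias_logit_sd = wbias_logit_sd, m_sd = m_sd,
              k_meanlog = k_meanlog, k_sdlog = k_sdlog, gamma = gamma,
              sigma_report = sigma_report,
              miss_probability = miss_probability,
              rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
              variant = variant)
  if (!all(vapply(cfg[2:8], is.finite, logical(1))))
    stop("coupling coefficients must be finite")
  structure(cfg, class = "population_config")
}

# factor scores with the configured quadratic/linear/correlation structure
.generate_profiles <- function(cfg) {
  n <- cfg$n_subjects
  z <- rnorm(n)                        # political orientation
  z2s <- (z^2 - 1) / sqrt(2)           # standardized quadratic component
  e_d <- rnorm(n)
  b_quad <- cfg$quad_coef
  dogma <- b_quad * z2s + sqrt(max(0, 1 - b_quad^2)) * e_d
  # authoritarianism: linear in orientation plus a share of dogmatism's
  # unique noise chosen so that cor(auth, dogma) = factor_cor
  b_lin <- cfg$lin_coef
  b_cor <- cfg$factor_cor / sqrt(max(1e-12, 1 - b_quad^2))
  resid_var <- 1 - b_lin^2 - b_cor^2
  if (resid_var < 0) stop("incompatible factor structure coefficients")
  auth <- b_lin * z + b_cor * e_d + sqrt(resid_var) * rnorm(n)
  data.frame(subject_id = seq_len(n),
             political_orientation = z,
             dogmatic_intolerance = dogma,
             authoritarianism = auth,
             age = sample(18:70, n, replace = TRUE),
             gender = sample(1:2, n, replace = TRUE),
             education = sample(1:5, n, replace = TRUE))
}

#' Composite radicalism score
#'
#' Sum of the z-scored dogmatic-intolerance and authoritarianism factor
#' scores.
#'
#' @param profiles Data frame with `dogmatic_intolerance` and
#'   `authoritarianism` columns.
#' @export
composite_radicalism <- function(profiles) {
  if (is.null(profiles$dogmatic_intolerance) ||
      is.null(profiles$authoritarianism))
    stop("profiles must contain dogmatic_intolerance and authoritarianism")
  scale(profiles$dogmatic_intolerance)[, 1] +
    scale(profiles$authoritarianism)[, 1]
}

#' Generate a synthetic population with planted radicalism structure
#'
#' Draws radicalism profiles with the configured factor interrelations,
#' couples each subject's generating choice-bias weight (on the logit
#' scale) to composite radicalism, and simulates every subject's full
#' session (calibration, confidence task, post-decision evidence task).
#' Ground-truth observer parameters are retained for recovery tests.
#'
#' @param config A [population_config()].
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return List of class `population` with `trials` (all subjects' trial
#'   records), `profiles` (factor scores, covariates and composite),
#'   `observers` (ground-truth observer specs, post-calibration),
#'   `calibration` (per-subject converged strengths and accuracies) and
#'   `config`.
#' @export
generate_population <- function(config = population_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n <- cfg$n_subjects
  profiles <- .generate_profiles(cfg)
  profiles$composite_radicalism <- composite_radicalism(profiles)
  zc <- scale(profiles$composite_radicalism)[, 1]
  rho <- cfg$wbias_coupling
  logit_w <- qlogis(cfg$wbias_mean) + cfg$wbias_logit_sd *
    (rho * zc + sqrt(max(0, 1 - rho^2)) * rnorm(n))
  w_bias <- plogis(logit_w)
  k <- rlnorm(n, cfg$k_meanlog, cfg$k_sdlog)
  m <- rnorm(n, 0, cfg$m_sd)
  observers <- vector("list", n)
  cal_rows <- vector("list", n)
  trial_rows <- vector("list", n)
  for (j in seq_len(n)) {
    vp <- switch(cfg$variant,
      base = variant_params("base"),
      choice_bias = variant_params("choice_bias", w_bias = w_bias[j]),
      temporal_weighting = variant_params("temporal_weighting",
                                          w_pre = 1, w_post = 1),
      choice_weighting = variant_params("choice_weighting",
                                        w_confirmatory = 1,
                                        w_disconfirmatory = 1),
      stop("unknown variant: ", cfg$variant))
    obs <- observer_spec(
      k = k[j], gamma = cfg$gamma,
      params = subject_model_params(m = m[j],
                                    sigma_report = cfg$sigma_report,
                                    variant_params = vp),
      rt_meanlog = cfg$rt_meanlog, rt_sdlog = cfg$rt_sdlog,
      miss_probability = cfg$miss_probability)
    sim <- simulate_subject(obs, subject_id = j)
    observers[[j]] <- sim$observer
    trial_rows[[j]] <- sim$trials
    cal_rows[[j]] <- data.frame(
      subject_id = j,
      low_log_strength = sim$calibration$low_log_strength,
      high_log_strength = sim$calibration$high_log_strength,
      acc_low = sim$calibration$acc_low,
      acc_high = sim$calibration$acc_high)
  }
  profiles$w_bias_true <- if (cfg$variant == "choice_bias") w_bias else NA
  structure(list(trials = do.call(rbind, trial_rows),
                 profiles = profiles,
                 observers = observers,
                 calibration = do.call(rbind, cal_rows),
                 config = cfg),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Synthetic population:", x$config$n_subjects, "subjects,",
      nrow(x$trials), "trial rows, generating variant:",
      x$config$variant, "\n")
  invisible(x)
}
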