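#' Per-subject metacognition and integration summary table
#'
#' Computes, for every subject: type-1 d-prime in each task and their mean,
#' the pooled criterion, task-1 meta-d-prime and confidence bias,
#' confirmatory and disconfirmatory integration slopes, post-decision
#' evidence sensitivity, quadratic-scoring-rule earnings, the converged
#' stimulus strength and high-strength performance, and the quantities the
#' exclusion screen consumes.
#'
#' @param population A `population` (or plain trial data frame with
#'   `subject_id`; calibration strengths are then recovered from the
#'   calibration rows).
#' @return Data frame, one row per subject.
#' @export
subject_summaries <- function(population) {
  trials <- if (inherits(population, "population")) population$trials
            else population
  cal <- if (inherits(population, "population")) population$calibration
         else NULL
  rows <- lapply(split(trials, trials$subject_id), function(tr) {
    id <- tr$subject_id[1]
    t1 <- tr[tr$phase == "task1", , drop = FALSE]
    t2 <- tr[tr$phase == "task2", , drop = FALSE]
    task <- tr[tr$phase %in% c("task1", "task2"), , drop = FALSE]
    cal_hi <- tr[tr$phase == "calibration" & tr$stim_level == "high", ,
                 drop = FALSE]
    d1 <- dprime_criterion(t1)
    d2 <- dprime_criterion(t2)
    md <- tryCatch(meta_d(t1), error = function(e)
      list(meta_d = NA_real_, flag = conditionMessage(e)))
    sc <- task[!task$missed & !is.na(task$choice), , drop = FALSE]
    rated <- sc$confidence[!is.na(sc$confidence)]
    if (!is.null(cal)) {
      crow <- cal[cal$subject_id == id, , drop = FALSE]
      log_strength <- crow$low_log_strength[1]
      acc_high <- crow$acc_high[1]
    } else {
      log_strength <- mean(task$log_strength_pre)
      acc_high <- if (nrow(cal_hi)) mean(cal_hi$accuracy, na.rm = TRUE)
                  else NA_real_
    }
    data.frame(
      subject_id = id,
      dprime_task1 = d1$dprime,
      dprime_task2 = d2$dprime,
      dprime_mean = (d1$dprime + d2$dprime) / 2,
      criterion = dprime_criterion(task)$criterion,
      meta_d = md$meta_d,
      meta_d_flag = md$flag,
      confidence_bias = confidence_bias(t1),
      beta_confirmatory = as.numeric(integration_betas(task, "correct")),
      beta_disconfirmatory = as.numeric(integration_betas(task, "incorrect")),
      pde_sensitivity = as.numeric(pde_sensitivity(t2)),
      earnings = earnings(task),
      log_strength = log_strength,
      acc_high = acc_high,
      accuracy = mean(sc$choice == sc$d),
      modal_rating_share = if (length(rated))
        max(table(rated)) / length(rated) else NA_real_,
      median_confidence_rt = median(sc$confidence_rt_ms, na.rm = TRUE),
      missed_fraction = mean(task$missed),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# regression 3 predictor block (behavioral battery + demographics)
.battery_predictors <- function(summaries, profiles) {
  data.frame(meta_d = summaries$meta_d,
             confidence_bias = summaries$confidence_bias,
             beta_confirmatory = summaries$beta_confirmatory,
             beta_disconfirmatory = summaries$beta_disconfirmatory,
             dprime_mean = summaries$dprime_mean,
             log_strength = summaries$log_strength,
             acc_high = summaries$acc_high,
             age = profiles$age,
             gender = profiles$gender,
             education = profiles$education)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a population, applies the exclusion screen, computes the
#' per-subject metric battery, runs the group-level regression battery
#' (factor interrelations; post-decision evidence sensitivity on task-1
#' metacognition; each radicalism facet on the metric battery plus
#' demographics; earnings on radicalism), and optionally fits the three
#' model variants to produce the radicalism BIC comparison and a
#' posterior-predictive decile table.
#'
#' @param config A [population_config()].
#' @param seed Integer seed governing every stochastic stage.
#' @param do_fits Fit model variants and run the BIC comparison /
#'   posterior predictive (default `TRUE`; the regression battery alone is
#'   much faster).
#' @param fit_cfg A [fit_config()] for the per-subject fits.
#' @param n_draws,n_trials_pp Posterior-predictive scale per subject.
#' @param tails Tail convention for the battery regressions.
#' @param out_dir If non-`NULL`, the report is written there as JSON plus
#'   CSV tables.
#' @return List of class `pipeline_report`.
#' @export
run_full_pipeline <- function(config = population_config(), seed = 1L,
                              do_fits = TRUE, fit_cfg = fit_config(),
                              n_draws = 100L, n_trials_pp = 4000L,
                              tails = "two", out_dir = NULL) {
  set.seed(seed)
  log_lines <- character(0)
  # no timestamps: a fixed seed must yield a byte-identical report
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  say("stage: simulate population (n = ", config$n_subjects, ")")
  pop <- generate_population(config)
  say("stage: exclusion screen")
  excl <- apply_exclusions(pop$trials)
  keep <- excl$retained
  say("  retained ", length(keep), " of ", config$n_subjects, " subjects")
  trials <- pop$trials[pop$trials$subject_id %in% keep, , drop = FALSE]
  profiles <- pop$profiles[pop$profiles$subject_id %in% keep, , drop = FALSE]
  say("stage: per-subject metrics")
  summaries <- subject_summaries(
    structure(list(trials = trials,
                   calibration = pop$calibration[
                     pop$calibration$subject_id %in% keep, , drop = FALSE]),
              class = "population"))
  composite <- composite_radicalism(profiles)
  say("stage: regression battery")
  interrelations <- list(
    orientation_dogmatism = quad_vs_linear(profiles$political_orientation,
                                           profiles$dogmatic_intolerance),
    orientation_authoritarianism = quad_vs_linear(
      profiles$political_orientation, profiles$authoritarianism),
    dogmatism_authoritarianism = robust_regress(
      profiles$authoritarianism,
      data.frame(dogmatic_intolerance = profiles$dogmatic_intolerance)))
  ok <- !is.na(summaries$meta_d)
  pde_reg <- robust_regress(
    summaries$pde_sensitivity[ok],
    data.frame(meta_d = summaries$meta_d[ok],
               dprime_mean = summaries$dprime_mean[ok],
               confidence_bias = summaries$confidence_bias[ok],
               log_strength = summaries$log_strength[ok],
               acc_high = summaries$acc_high[ok]),
    tails = tails)
  X <- .battery_predictors(summaries[ok, ], profiles[ok, ])
  factor_regs <- list(
    dogmatic_intolerance = robust_regress(
      profiles$dogmatic_intolerance[ok], X, tails = tails),
    authoritarianism = robust_regress(
      profiles$authoritarianism[ok], X, tails = tails),
    political_orientation = robust_regress(
      profiles$political_orientation[ok], X, tails = tails),
    composite = robust_regress(composite[ok], X, tails = tails))
  earnings_reg <- robust_regress(
    summaries$earnings,
    data.frame(composite_radicalism = composite,
               dprime_mean = summaries$dprime_mean,
               log_strength = summaries$log_strength),
    tails = tails)
  model_comparison <- fits <- predictive <- NULL
  if (do_fits) {
    say("stage: model fits (3 variants x ", length(keep), " subjects)")
    fits <- lapply(setNames(nm = c("temporal_weighting", "choice_weighting",
                                   "choice_bias")),
                   function(v) fit_population(trials, variant = v,
                                              config = fit_cfg))
    say("stage: BIC model comparison")
    model_comparison <- compare_models_radicalism(fits, composite)
    say("stage: posterior predictive")
    predictive <- posterior_predictive(fits$choice_bias, composite,
                                       n_draws = n_draws,
                                       n_trials = n_trials_pp)
  }
  report <- structure(list(
    config = config, seed = seed,
    exclusions = excl,
    summaries = summaries,
    profiles = profiles,
    composite = composite,
    interrelations = interrelations,
    pde_regression = pde_reg,
    factor_regressions = factor_regs,
    earnings_regression = earnings_reg,
    fits = fits,
    model_comparison = model_comparison,
    posterior_predictive = predictive,
    log = log_lines), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report: n =", nrow(x$summaries), "retained subjects\n")
  cat("Dogmatic intolerance battery betas:\n")
  print(x$factor_regressions$dogmatic_intolerance)
  if (!is.null(x$model_comparison)) {
    cat("Radicalism model comparison (delta BIC):\n")
    print(x$model_comparison, row.names = FALSE)
  }
  invisible(x)
}

# serializable view of a regression result
.reg_to_list <- function(r) {
  list(coefficients = r$coefficients, n = r$n, r2 = r$r2, bic = r$bic,
       vif = as.list(r$vif))
}

#' Write a pipeline report to disk (JSON + CSV tables)
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$summaries, file.path(dir, "subject_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions$flags,
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  if (!is.null(report$model_comparison))
    utils::write.csv(report$model_comparison,
                     file.path(dir, "model_comparison.csv"),
                     row.names = FALSE)
  if (!is.null(report$posterior_predictive))
    utils::write.csv(report$posterior_predictive,
                     file.path(dir, "posterior_predictive.csv"),
                     row.names = FALSE)
  json <- list(
    seed = report$seed,
    n_retained = length(report$exclusions$retained),
    exclusion_counts = as.list(report$exclusions$counts),
    interrelations = lapply(report$interrelations, function(x)
      if (!is.null(x$label)) list(label = x$label,
                                  fit = .reg_to_list(x$fit))
      else .reg_to_list(x)),
    pde_regression = .reg_to_list(report$pde_regression),
    factor_regressions = lapply(report$factor_regressions, .reg_to_list),
    earnings_regression = .reg_to_list(report$earnings_regression),
    model_comparison = report$model_comparison,
    log = report$log)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
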