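.trial_columns <- c("subject_id", "phase", "trial", "d", "log_strength_pre",
                    "post_level", "choice", "accuracy", "confidence",
                    "confidence_rt_ms", "missed")

# the pre-decision stimulus-strength level ("low"/"high"); "high" only for
# the 50 high-strength calibration judgements, which feed the d-prime
# constraint on mu_high and the high-strength performance regressor
.stim_column <- "stim_level"

# flatten an observer spec to a plain list for the JSON sidecar
.observer_to_list <- function(obs) {
  p <- obs$params
  vp <- p$variant_params
  c(list(k = obs$k, gamma = obs$gamma,
         m = p$m, mu_low = p$strengths$mu_low,
         mu_high = p$strengths$mu_high,
         sigma_report = p$sigma_report,
         rt_meanlog = obs$rt_meanlog, rt_sdlog = obs$rt_sdlog,
         miss_probability = obs$miss_probability,
         variant = vp$variant),
    vp[setdiff(names(vp), "variant")])
}

.observer_from_list <- function(l) {
  vp <- do.call(variant_params,
                c(list(variant = l$variant),
                  l[intersect(names(l), c("w_pre", "w_post",
                                          "w_confirmatory",
                                          "w_disconfirmatory", "w_bias"))]))
  observer_spec(k = l$k, gamma = l$gamma,
                params = subject_model_params(
                  m = l$m,
                  strengths = evidence_strengths(l$mu_low, l$mu_high),
                  sigma_report = l$sigma_report,
                  variant_params = vp),
                rt_meanlog = l$rt_meanlog, rt_sdlog = l$rt_sdlog,
                miss_probability = l$miss_probability)
}

#' Write a population dataset to disk
#'
#' Trial records go to `trials.csv` (fixed column order), radicalism
#' profiles, ground-truth observer parameters, per-subject calibration
#' results and the generating configuration to a JSON sidecar
#' `ground_truth.json`.
#'
#' @param population A `population` as returned by [generate_population()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- population$trials[, c(.trial_columns, .stim_column)]
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  sidecar <- list(
    profiles = population$profiles,
    observers = lapply(population$observers, .observer_to_list),
    calibration = population$calibration,
    config = unclass(population$config))
  jsonlite::write_json(sidecar, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a population dataset written by [write_dataset()]
#'
#' @param dir Directory containing `trials.csv` and `ground_truth.json`.
#' @return A `population` object; ratings are re-snapped onto the 9-point
#'   grid to absorb decimal round-trip error.
#' @export
read_dataset <- function(dir) {
  csv <- file.path(dir, "trials.csv")
  if (!file.exists(csv)) stop("no trials.csv in ", dir)
  trials <- utils::read.csv(csv, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols))
    stop("trials.csv is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_phase <- setdiff(unique(trials$phase),
                       c("calibration", "task1", "task2"))
  if (length(bad_phase))
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "))
  if (is.null(trials[[.stim_column]])) {
    warning("trials.csv has no stim_level column; assuming all low strength")
    trials[[.stim_column]] <- "low"
  }
  ok <- !is.na(trials$confidence)
  trials$confidence[ok] <- snap_rating(trials$confidence[ok])
  side <- file.path(dir, "ground_truth.json")
  profiles <- observers <- calibration <- cfg <- NULL
  if (file.exists(side)) {
    gt <- jsonlite::read_json(side, simplifyVector = TRUE)
    profiles <- gt$profiles
    calibration <- gt$calibration
    if (!is.null(gt$config))
      cfg <- do.call(population_config, gt$config)
    if (!is.null(gt$observers)) {
      obs_list <- gt$observers
      if (is.data.frame(obs_list))
        obs_list <- split(obs_list, seq_len(nrow(obs_list)))
      observers <- lapply(obs_list, function(o)
        .observer_from_list(as.list(o)))
    }
  }
  structure(list(trials = trials, profiles = profiles,
                 observers = observers, calibration = calibration,
                 config = cfg),
            class = "population")
}
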