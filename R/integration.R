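# evidence code: confidence task = 0, low post-decision evidence = 1,
# high post-decision evidence = 2
.evidence_code <- function(trials) {
  code <- rep(NA_real_, nrow(trials))
  code[trials$post_level == "none"] <- 0
  code[trials$post_level == "low"] <- 1
  code[trials$post_level == "high"] <- 2
  code
}

#' Confirmatory / disconfirmatory evidence-integration slope
#'
#' Per-subject OLS regression of confidence on the post-decision evidence
#' code (confidence task = 0, low = 1, high = 2) over trials pooled from
#' both tasks, separately per accuracy class. For correct trials the raw
#' slope measures confirmatory integration; for incorrect trials the
#' returned value is the negated slope, so that larger values always mean
#' more integration of the evidence.
#'
#' @param trials Trial records pooled from tasks 1 and 2.
#' @param accuracy_class `"correct"` or `"incorrect"`.
#' @return Slope in confidence-probability units per evidence level, or
#'   `NA` with a `"flag"` attribute when fewer than two evidence levels are
#'   present in the class.
#' @export
integration_betas <- function(trials, accuracy_class = c("correct", "incorrect")) {
  accuracy_class <- match.arg(accuracy_class)
  tr <- .scored_trials(trials, rated = TRUE)
  tr <- tr[tr$phase %in% c("task1", "task2"), , drop = FALSE]
  acc <- tr$choice == tr$d
  tr <- tr[if (accuracy_class == "correct") acc else !acc, , drop = FALSE]
  code <- .evidence_code(tr)
  if (length(unique(code[!is.na(code)])) < 2L) {
    out <- NA_real_
    attr(out, "flag") <- "single_evidence_level"
    return(out)
  }
  slope <- unname(coef(lm(tr$confidence ~ code))[2])
  if (accuracy_class == "incorrect") -slope else slope
}

#' Overall sensitivity to post-decision evidence
#'
#' OLS coefficient of the accuracy-by-strength interaction in a per-subject
#' trial-level model of confidence on accuracy (correct = 1, incorrect =
#' -1), post-decision evidence strength (low = 1, high = 2) and their
#' interaction, computed solely from task-2 trials so the measure is
#' independent of task-1-based metacognition estimates.
#'
#' @param trials Trial records; only `phase == "task2"` rows are used.
#' @return Interaction coefficient, or `NA` flagged
#'   `"missing_accuracy_or_strength_class"` when either accuracy class or
#'   either strength is absent.
#' @export
pde_sensitivity <- function(trials) {
  tr <- .scored_trials(trials, rated = TRUE)
  tr <- tr[tr$phase == "task2", , drop = FALSE]
  acc <- ifelse(tr$choice == tr$d, 1, -1)
  strength <- ifelse(tr$post_level == "high", 2, 1)
  if (length(unique(acc)) < 2L || length(unique(strength)) < 2L) {
    out <- NA_real_
    attr(out, "flag") <- "missing_accuracy_or_strength_class"
    return(out)
  }
  fit <- lm(tr$confidence ~ acc + strength + acc:strength)
  unname(coef(fit)["acc:strength"])
}
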