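# non-missed trials with a choice; optionally requiring a rating
.scored_trials <- function(trials, rated = FALSE) {
  keep <- !trials$missed & !is.na(trials$choice)
  if (rated) keep <- keep & !is.na(trials$confidence)
  trials[keep, , drop = FALSE]
}

#' Type-1 sensitivity and criterion
#'
#' Equal-variance signal-detection d-prime and criterion from a block of
#' trials, treating "right" (`d = +1`) as the signal class. Extreme rates
#' are handled by adding 0.5 to every cell of the 2x2 stimulus-by-response
#' table (log-linear padding), so hit rates of 0 or 1 stay finite.
#'
#' @param trials Trial records with columns `d`, `choice`, `missed`.
#' @return List with `dprime` and `criterion`.
#' @export
dprime_criterion <- function(trials) {
  tr <- .scored_trials(trials)
  if (!all(c(-1, 1) %in% tr$d))
    stop("both true sides must be present to compute d-prime")
  n_hit <- sum(tr$d == 1 & tr$choice == 1) + 0.5
  n_sig <- sum(tr$d == 1) + 1
  n_fa <- sum(tr$d == -1 & tr$choice == 1) + 0.5
  n_noise <- sum(tr$d == -1) + 1
  h <- n_hit / n_sig
  fa <- n_fa / n_noise
  list(dprime = qnorm(h) - qnorm(fa),
       criterion = -0.5 * (qnorm(h) + qnorm(fa)))
}

# response-conditional confidence probabilities of the meta-level SDT
# observer: means +/- meta_d/2, type-1 split at meta_c, K-1 type-2
# boundaries per response side
.meta_cond_probs <- function(meta_d, meta_c, inc_r2, inc_r1, K) {
  b <- meta_c + cumsum(inc_r2)              # boundaries above, R = +1
  cc <- meta_c - cumsum(inc_r1)             # boundaries below, R = -1
  out <- array(NA_real_, dim = c(2, 2, K))  # [stim, resp, bin]
  for (si in 1:2) {
    mu <- c(-meta_d / 2, meta_d / 2)[si]
    hi <- c(pnorm(b - mu), 1)
    lo0 <- pnorm(meta_c - mu)
    p_r2 <- diff(c(lo0, hi))                 # bins 1..K for R = +1
    lo <- c(pnorm(cc - mu), 0)
    p_r1 <- -diff(c(lo0, lo))                # bins 1..K for R = -1
    out[si, 2, ] <- p_r2 / max(1 - lo0, 1e-12)
    out[si, 1, ] <- p_r1 / max(lo0, 1e-12)
  }
  pmax(out, 1e-12)
}

#' Maximum-likelihood meta-d-prime
#'
#' Estimates metacognitive sensitivity as the type-1 d-prime an ideal
#' signal-detection observer would need, given the subject's type-1
#' criterion, to produce the observed response-conditional confidence
#' distributions. Confidence ratings are binned on the 9-point grid
#' (collapsing automatically to the set of ratings the subject actually
#' used); type-2 criteria are free parameters and the multinomial
#' likelihood is maximized over meta-d-prime and the criteria, with a
#' padding of `1/(2 * n_bins)` added to every stimulus-response-bin cell.
#'
#' @param trials Trial records with `d`, `choice`, `confidence`, `missed`.
#' @param n_bins Maximum number of confidence bins (default 9, the rating
#'   grid).
#' @return List with `meta_d`, the type-1 `dprime` and `criterion`, the
#'   number of bins used, and `flag` (`"ok"` or `"degenerate_confidence"`
#'   when a single rating was used, in which case `meta_d` is `NA`).
#' @export
meta_d <- function(trials, n_bins = 9L) {
  tr <- .scored_trials(trials, rated = TRUE)
  if (nrow(tr) == 0L) stop("no rated trials")
  acc <- as.integer(tr$choice == tr$d)
  if (!any(acc == 1L) || !any(acc == 0L))
    stop("need at least one correct and one incorrect rated trial")
  t1 <- dprime_criterion(tr)
  lev <- sort(unique(tr$confidence))
  if (length(lev) < 2L)
    return(list(meta_d = NA_real_, dprime = t1$dprime,
                criterion = t1$criterion, n_bins_used = length(lev),
                flag = "degenerate_confidence"))
  if (length(lev) > n_bins) {
    cuts <- quantile(tr$confidence, probs = seq(0, 1, length.out = n_bins + 1))
    bin <- as.integer(cut(tr$confidence, unique(cuts), include.lowest = TRUE))
  } else {
    bin <- match(tr$confidence, lev)
  }
  K <- max(bin)
  counts <- array(1 / (2 * K), dim = c(2, 2, K))
  si <- ifelse(tr$d == 1, 2L, 1L)
  ri <- ifelse(tr$choice == 1, 2L, 1L)
  for (i in seq_along(bin))
    counts[si[i], ri[i], bin[i]] <- counts[si[i], ri[i], bin[i]] + 1
  c_rel <- t1$criterion / t1$dprime
  negll <- function(par) {
    md <- par[1]
    mc <- c_rel * md
    p <- .meta_cond_probs(md, mc, exp(par[2:K]), exp(par[(K + 1):(2 * K - 1)]), K)
    -sum(counts * log(p))
  }
  start <- c(t1$dprime, rep(log(3 / (K - 1)), 2 * (K - 1)))
  fit <- nlminb(start, negll, control = list(iter.max = 500))
  # one restart from a flatter configuration guards against local optima
  fit2 <- nlminb(c(0.5 * t1$dprime, rep(log(1.5 / (K - 1)), 2 * (K - 1))),
                 negll, control = list(iter.max = 500))
  if (fit2$objective < fit$objective) fit <- fit2
  list(meta_d = fit$par[1], dprime = t1$dprime, criterion = t1$criterion,
       n_bins_used = K, flag = "ok")
}

#' Confidence bias (over/underconfidence)
#'
#' Default operationalization: mean confidence minus proportion correct
#' over rated trials (positive values indicate overconfidence). The
#' alternative `"raw"` method returns mean confidence alone.
#'
#' @param trials Trial records.
#' @param method `"relative"` (default) or `"raw"`.
#' @export
confidence_bias <- function(trials, method = c("relative", "raw")) {
  method <- match.arg(method)
  tr <- .scored_trials(trials, rated = TRUE)
  if (nrow(tr) == 0L) stop("no rated trials")
  mc <- mean(tr$confidence)
  if (method == "raw") return(mc)
  mc - mean(tr$choice == tr$d)
}

#' Quadratic-scoring-rule earnings
#'
#' Per-trial points are `1 - (accuracy - confidence)^2`: maximal when
#' maximally confident and correct or minimally confident and wrong.
#'
#' @param trials Trial records with ratings.
#' @param scale Multiplier applied to the summed points (default 1).
#' @export
earnings <- function(trials, scale = 1) {
  tr <- .scored_trials(trials, rated = TRUE)
  if (nrow(tr) == 0L) stop("no rated trials")
  acc <- as.numeric(tr$choice == tr$d)
  scale * sum(1 - (acc - tr$confidence)^2)
}
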