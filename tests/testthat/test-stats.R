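test_that("robust regression returns standardized betas and matches OLS on
           clean data", {
  set.seed(71)
  x <- rnorm(50)
  y <- 2 * x
  fit <- robust_regress(y, data.frame(x = x))
  expect_equal(fit$coefficients$beta, 1, tolerance = 1e-8)
  # recovered unstandardized slope
  expect_equal(fit$coefficients$beta * sd(y) / sd(x), 2, tolerance = 1e-8)
  # agreement with least squares on well-behaved data (bisquare weights
  # are all 1 only at zero residuals, so equality is exact for perfect
  # fits and close otherwise)
  y2 <- x + rnorm(50, 0, 0.2)
  rob <- robust_regress(y2, data.frame(x = x))
  ols <- coef(lm(scale(y2) ~ scale(x)))[2]
  expect_equal(rob$coefficients$beta, unname(ols), tolerance = 0.02)
  exact <- robust_regress(3 * x - 1, data.frame(x = x))
  ols2 <- coef(lm(scale(3 * x - 1) ~ scale(x)))[2]
  expect_equal(exact$coefficients$beta, unname(ols2), tolerance = 1e-6)
})

test_that("bisquare weighting resists a gross outlier", {
  set.seed(72)
  x <- rnorm(50)
  y <- x + rnorm(50, 0, 0.1)
  y[1] <- 15
  rob <- robust_regress(y, data.frame(x = x))$coefficients$beta
  ols <- unname(coef(lm(scale(y) ~ scale(x)))[2])
  slope_rob <- rob * sd(y) / sd(x)
  slope_ols <- ols * sd(y) / sd(x)
  expect_lt(abs(slope_rob - 1), abs(slope_ols - 1))
})

test_that("design-matrix pathologies are rejected", {
  x <- rnorm(30)
  expect_error(robust_regress(x + rnorm(30),
                              data.frame(a = x, b = x)),
               "rank-deficient")
  expect_error(robust_regress(rnorm(30),
                              data.frame(a = x, b = rep(1, 30))),
               "constant predictor")
  expect_error(robust_regress(rnorm(3), data.frame(a = rnorm(3),
                                                   b = rnorm(3))),
               "n >")
})

test_that("one-tailed p-values halve when the sign matches the hypothesis", {
  set.seed(73)
  x <- rnorm(200)
  y <- 0.3 * x + rnorm(200)
  two <- robust_regress(y, data.frame(x = x))
  one <- robust_regress(y, data.frame(x = x), tails = "one",
                        directions = c(x = 1))
  expect_equal(one$coefficients$p, two$coefficients$p / 2)
  wrong <- robust_regress(y, data.frame(x = x), tails = "one",
                          directions = c(x = -1))
  expect_equal(wrong$coefficients$p, 1 - two$coefficients$p / 2)
})

test_that("variance inflation factors follow 1 / (1 - R2)", {
  set.seed(74)
  n <- 400
  e1 <- rnorm(n); e2 <- rnorm(n)
  # construct exact correlation 0.6 by orthogonalization
  e1 <- scale(e1)[, 1]
  e2 <- scale(resid(lm(e2 ~ e1)))[, 1]
  x2 <- 0.6 * e1 + sqrt(1 - 0.36) * e2
  v <- vif(data.frame(a = e1, b = x2))
  expect_equal(unname(v), c(1.5625, 1.5625), tolerance = 1e-6)
  # orthogonal predictors
  v0 <- vif(data.frame(a = e1, b = e2))
  expect_equal(unname(v0), c(1, 1), tolerance = 1e-6)
  # perfect collinearity is flagged
  vv <- suppressWarnings(vif(data.frame(a = e1, b = e1)))
  expect_true(any(!is.finite(vv)))
  expect_equal(attr(vv, "flag"), "perfect_collinearity")
  expect_error(vif(data.frame(a = e1)), ">= 2")
})

test_that("partial R2 is the nested difference in explained variance", {
  set.seed(75)
  x1 <- rnorm(300); x2 <- rnorm(300)
  y <- 0.5 * x1 + rnorm(300)
  full <- robust_regress(y, data.frame(x1 = x1, x2 = x2))
  red <- robust_regress(y, data.frame(x1 = x1))
  expect_lt(abs(partial_r2(full, red)), 0.02)        # x2 is pure noise
  expect_equal(partial_r2(full, full), 0)
  single <- robust_regress(2 * x1, data.frame(x1 = x1))
  expect_equal(single$r2, 1, tolerance = 1e-8)
  expect_error(partial_r2(red, full), "not nested")
})

test_that("regression BIC follows the Gaussian-likelihood convention", {
  expect_equal(regression_bic(list(n = 100, rss = 100, k = 1)),
               3 * log(100))
  expect_error(regression_bic(list(n = 10, rss = 0, k = 1)), "positive")
  # a pure-noise predictor increases BIC in expectation
  set.seed(76)
  diffs <- replicate(40, {
    x <- rnorm(80); y <- 0.5 * x + rnorm(80)
    b1 <- robust_regress(y, data.frame(x = x))$bic
    b2 <- robust_regress(y, data.frame(x = x, z = rnorm(80)))$bic
    b2 - b1
  })
  expect_gt(mean(diffs), 0)
})

test_that("linear and quadratic relations are labelled by BIC", {
  set.seed(77)
  x <- rnorm(300)
  expect_equal(quad_vs_linear(x, x^2 + rnorm(300, 0, 0.3))$label,
               "quadratic")
  expect_equal(quad_vs_linear(x, x + rnorm(300, 0, 0.3))$label, "linear")
  const <- quad_vs_linear(x, rep(1, 300))
  expect_equal(const$label, "linear")
  expect_equal(const$fit$coefficients$beta, 0, tolerance = 1e-8)
  expect_error(quad_vs_linear(rep(1, 50), rnorm(50)), "degenerate")
  expect_error(quad_vs_linear(rnorm(5), rnorm(5)), "n >= 10")
})

test_that("composite radicalism sums the z-scored facets", {
  pr <- data.frame(dogmatic_intolerance = c(1, -1, 0, 2, -2),
                   authoritarianism = c(1, 1, 0, -2, 0))
  comp <- composite_radicalism(pr)
  zd <- scale(pr$dogmatic_intolerance)[, 1]
  za <- scale(pr$authoritarianism)[, 1]
  expect_equal(comp, zd + za)
  expect_equal(mean(comp), 0, tolerance = 1e-12)
  expect_error(composite_radicalism(data.frame(x = 1)), "must contain")
})

test_that("the exclusion screen flags each planted violation once", {
  cohort <- make_exclusion_cohort()
  rep <- apply_exclusions(cohort)
  expect_equal(unname(rep$counts[["excluded"]]), 5)
  expect_equal(sort(rep$retained), 6:10)
  f <- rep$flags
  expect_true(f$performance_out_of_range[f$subject_id == 1])
  expect_true(f$performance_out_of_range[f$subject_id == 2])
  expect_true(f$single_rating[f$subject_id == 3])
  expect_true(f$fast_confidence_rt[f$subject_id == 4])
  expect_true(f$missed_trials[f$subject_id == 5])
  expect_equal(unname(colSums(f[, 2:5])), c(2, 1, 1, 1))
})

test_that("exclusion thresholds are strict inequalities", {
  n <- 200L
  d <- rep(c(-1, 1), n / 2)
  mk <- function(id, n_correct) {
    make_trials(d, ifelse(seq_len(n) <= n_correct, d, -d),
                confidence = rep(seq(0.125, 1, 0.125), length.out = n))
  }
  tr <- mk(1, 170)   # exactly 85%: retained
  tr$subject_id <- 1
  rep1 <- apply_exclusions(tr)
  expect_equal(rep1$retained, 1)
  tr2 <- mk(1, 120)  # exactly 60%: retained
  rep2 <- apply_exclusions(tr2)
  expect_equal(rep2$retained, 1)
  # clean cohort: nothing flagged
  clean <- make_exclusion_cohort()
  clean <- clean[clean$subject_id >= 6, ]
  expect_equal(unname(apply_exclusions(clean)$counts[["excluded"]]), 0)
})

test_that("the radicalism model comparison reports a zero-anchored BIC
           table", {
  set.seed(78)
  n <- 60
  mk_fits <- function(variant, extra) {
    lapply(seq_len(n), function(j) {
      est <- list(m = rnorm(1, 0, 0.1), mu_low = rnorm(1, 0.6, 0.1),
                  mu_high = rnorm(1, 0.95, 0.1), sigma_report = 0.05)
      est <- c(est, as.list(setNames(rnorm(length(extra), 1, 0.2), extra)))
      structure(list(subject_id = j, variant = variant, estimates = est),
                class = "fit_result")
    })
  }
  fits <- list(
    temporal_weighting = mk_fits("temporal_weighting", c("w_pre", "w_post")),
    choice_weighting = mk_fits("choice_weighting",
                               c("w_confirmatory", "w_disconfirmatory")),
    choice_bias = mk_fits("choice_bias", "w_bias"))
  comp <- rnorm(n)
  tab <- compare_models_radicalism(fits, comp)
  expect_equal(min(tab$delta_bic), 0)
  expect_equal(nrow(tab), 7)
  expect_equal(tab$delta_bic, tab$bic - min(tab$bic))
  # mismatched subject sets across variants are rejected
  fits_bad <- fits
  fits_bad$choice_bias <- fits_bad$choice_bias[-1]
  expect_error(compare_models_radicalism(fits_bad, comp), "differ")
})
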