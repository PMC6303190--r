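test_that("mixture moments follow the equal-mixture mean and total variance", {
  mm <- mixture_moments(evidence_strengths(0.5, 1.5))
  expect_equal(mm$mu, 1.0)
  expect_equal(mm$sigma2, 1.25)
  mm2 <- mixture_moments(evidence_strengths(0.7, 0.7))
  expect_equal(mm2$mu, 0.7)
  expect_equal(mm2$sigma2, 1.0)
  mm3 <- mixture_moments(evidence_strengths(0.5, 1.0))
  expect_equal(mm3$mu, 0.75)
  expect_equal(mm3$sigma2, 1.0625)
  expect_error(evidence_strengths(-1, 1), "positive")
  expect_error(evidence_strengths(1, 0.5), ">=")
  expect_error(evidence_strengths(Inf, 1), "finite")
})

test_that("direction log-odds equal the Gaussian likelihood-ratio quotient", {
  expect_equal(lo_direction(0, list(mu = 1, sigma2 = 1)), 0)
  expect_equal(lo_direction(1, list(mu = 1, sigma2 = 1)), 2)
  expect_equal(lo_direction(0.5, list(mu = 1, sigma2 = 1.25)), 0.8)
  expect_error(lo_direction(1, list(mu = 1, sigma2 = 0)), "positive")
  # closed form vs direct quotient of Gaussian densities
  set.seed(11)
  x <- rnorm(1e4, 0, 3)
  mu <- runif(1e4, 0.05, 3)
  s2 <- runif(1e4, 1, 4)
  quotient <- dnorm(x, mu, sqrt(s2), log = TRUE) -
    dnorm(x, -mu, sqrt(s2), log = TRUE)
  closed <- mapply(function(xi, m, s)
    lo_direction(xi, list(mu = m, sigma2 = s)), x, mu, s2)
  expect_lt(max(abs(closed - quotient)), 1e-10)
})

test_that("log-odds correct condition on the action and are antisymmetric", {
  expect_equal(lo_correct(2, 1), 2)
  expect_equal(lo_correct(2, -1), -2)
  expect_equal(lo_correct(0, -1), 0)
  expect_error(lo_correct(1, 0), "-1 or \\+1")
  lo <- rnorm(50)
  expect_equal(lo_correct(lo, 1), -lo_correct(lo, -1))
})

test_that("combine_evidence implements the variant algebra", {
  mm <- list(mu = 1, sigma2 = 1)
  # base: additive Bayes; lo_pre = 1, lo_post = 0.5
  cc <- combine_evidence(list(x_pre = 0.5, x_post = 0.25, post_level = "low"),
                         base_params(), 1, mm)
  expect_equal(cc$lo_correct_total, 1.5)
  expect_equal(cc$confidence, plogis(1.5))
  # temporal: w_pre 1, w_post 0.5 with lo_post = -2 cancels lo_pre = 1
  tp <- subject_model_params(variant_params = variant_params(
    "temporal_weighting", w_pre = 1, w_post = 0.5))
  cc <- combine_evidence(list(x_pre = 0.5, x_post = -1, post_level = "low"),
                         tp, 1, mm)
  expect_equal(cc$lo_correct_total, 0)
  expect_equal(cc$confidence, 0.5)
  # choice bias adds logit(w_bias) to the direction log-odds
  cb <- cb_params(w_bias = 0.75)
  cc <- combine_evidence(list(x_pre = 0.5, x_post = 0.25, post_level = "low"),
                         cb, 1, mm)
  expect_equal(cc$lo_bias, log(3), tolerance = 1e-12)
  expect_equal(cc$lo_correct_total, 1.5 + log(3))
  # and flips sign with the action before conditioning
  cc_l <- combine_evidence(list(x_pre = -0.5, x_post = -0.25,
                                post_level = "low"), cb, -1, mm)
  expect_equal(cc_l$lo_bias, -log(3))
  expect_equal(cc_l$lo_correct_total, 1.5 + log(3))
  # choice weighting picks the disconfirmatory weight on sign mismatch
  cw <- subject_model_params(variant_params = variant_params(
    "choice_weighting", w_confirmatory = 1, w_disconfirmatory = 0.25))
  cc <- combine_evidence(list(x_pre = 0.5, x_post = -0.3, post_level = "low"),
                         cw, 1, mm)
  expect_equal(cc$lo_correct_total, 1 + 0.25 * (-0.6))
  expect_error(variant_params("choice_bias", w_bias = 1.2), "\\(0, 1\\)")
})

test_that("weight settings reduce the variants to the base model", {
  set.seed(12)
  mm <- mixture_moments(evidence_strengths(0.6, 0.95))
  tp <- subject_model_params(variant_params = variant_params(
    "temporal_weighting", w_pre = 1, w_post = 1))
  cb <- cb_params(w_bias = 0.5)
  bp <- base_params()
  for (i in 1:50) {
    x_pre <- rnorm(1); x_post <- rnorm(1)
    a <- sample(c(-1, 1), 1)
    smp <- list(x_pre = x_pre, x_post = x_post, post_level = "low")
    c0 <- combine_evidence(smp, bp, a, mm)$confidence
    expect_equal(combine_evidence(smp, tp, a, mm)$confidence, c0)
    expect_equal(combine_evidence(smp, cb, a, mm)$confidence, c0)
  }
})

test_that("confidence is monotone in total log-odds and in confirmatory evidence", {
  lo <- seq(-10, 10, by = 0.25)
  conf <- confidence_from_logodds(lo)
  expect_true(all(diff(conf) > 0))
  expect_equal(confidence_from_logodds(0), 0.5)
  expect_equal(confidence_from_logodds(log(3)), 0.75)
  expect_equal(confidence_from_logodds(1e6), 1 - 1e-6)
  expect_equal(confidence_from_logodds(-1e6), 1e-6)
  # confirmatory post-decision evidence never lowers base-model confidence
  mm <- mixture_moments(evidence_strengths(0.6, 0.95))
  bp <- base_params()
  for (x_pre in c(0.2, 1, 2)) {
    c_none <- combine_evidence(list(x_pre = x_pre, post_level = "none"),
                               bp, 1, mm)$confidence
    c_conf <- combine_evidence(list(x_pre = x_pre, x_post = 0.5,
                                    post_level = "low"), bp, 1, mm)$confidence
    expect_gte(c_conf, c_none)
  }
})

test_that("the decision rule is a step with a fair-coin tie-break", {
  expect_equal(decide(0.2, 0), 1)
  expect_equal(decide(-0.2, 0), -1)
  expect_equal(decide(c(1, 2), 1.5), c(-1, 1))
  set.seed(13)
  ties <- replicate(4000, decide(0.5, 0.5))
  expect_gt(mean(ties == 1), 0.45)
  expect_lt(mean(ties == 1), 0.55)
  # stochastic mode follows the softmax
  set.seed(14)
  p_up <- mean(replicate(4000, decide(0.001, 0, slope = 1000,
                                      deterministic = FALSE)) == 1)
  expect_equal(p_up, plogis(1), tolerance = 0.05)
  expect_error(decide(1, 0, slope = -1), "positive")
})

test_that("reports are snapped to the 9-point grid after clipping", {
  expect_equal(simulate_report(0.5, 0), 0.5)
  expect_equal(simulate_report(0.97, 0), 1.0)
  expect_equal(snap_rating(c(0.06, 0.07, 0.99, 0.01)),
               c(0, 0.125, 1, 0))
  set.seed(15)
  r <- simulate_report(rep(0.75, 2e4), 0.05)
  expect_true(all(r %in% seq(0, 1, by = 0.125)))
  expect_equal(mean(r), 0.75, tolerance = 0.01)
  expect_error(simulate_report(0.5, -0.1), ">= 0")
})
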