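test_that("the compiled likelihood equals the R reference quadrature", {
  p <- cb_params(w_bias = 0.65, m = 0.1)
  cfg <- fit_config()
  obs_list <- list(
    list(d = 1, post_level = "none", a = 1, r = 0.875),
    list(d = 1, post_level = "low", a = -1, r = 0.5),
    list(d = -1, post_level = "high", a = 1, r = 0.25),
    list(d = -1, post_level = "none", a = -1, r = 1))
  for (ob in obs_list) {
    ll_r <- trial_loglik(p, ob, n_nodes = 61)
    ll_c <- pdeconf:::cpp_loglik(as.integer(ob$d),
      match(ob$post_level, c("none", "low", "high")) - 1L,
      as.integer(ob$a), ob$r, 1, p$m, 0.6, 0.95, 0.05, 3L, 0.65, 0,
      61L, 61L)
    expect_equal(ll_r, ll_c, tolerance = 1e-10)
  }
  # temporal variant path
  tp <- subject_model_params(m = -0.1,
    strengths = evidence_strengths(0.5, 1.1), sigma_report = 0.08,
    variant_params = variant_params("temporal_weighting",
                                    w_pre = 0.8, w_post = 1.3))
  ob <- list(d = 1, post_level = "low", a = 1, r = 0.75)
  expect_equal(trial_loglik(tp, ob, 61),
               pdeconf:::cpp_loglik(1L, 1L, 1L, 0.75, 1, -0.1, 0.5, 1.1,
                                    0.08, 1L, 0.8, 1.3, 61L, 61L),
               tolerance = 1e-10)
})

test_that("outcome probabilities normalize and match the fitting likelihood", {
  p <- cb_params(w_bias = 0.65, m = 0.1)
  for (lev in c("none", "low", "high")) {
    op <- outcome_probs(p, d = 1, post_level = lev, n_nodes = 101)
    expect_equal(sum(op$prob), 1, tolerance = 1e-3)
  }
  # the fitting likelihood is the same snapped-outcome probability: summing
  # exp(loglik) over all (action, rating) outcomes gives 1, and each term
  # matches the independent R-side outcome_probs computation
  grid <- seq(0, 1, by = 0.125)
  total <- 0
  op <- outcome_probs(p, d = 1, post_level = "low", n_nodes = 61)
  for (a in c(-1L, 1L)) for (g in grid) {
    pr <- exp(pdeconf:::cpp_loglik(1L, 1L, a, g, 1, 0.1, 0.6, 0.95, 0.05,
                                   3L, 0.65, 0, 61L, 61L))
    total <- total + pr
    expect_equal(pr, op$prob[op$action == a & op$rating == g],
                 tolerance = 1e-6)
  }
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("a half-half bias weight gives the base-model likelihood", {
  for (ob in list(list(d = 1L, level = 0L, a = 1L, r = 0.625),
                  list(d = -1L, level = 2L, a = 1L, r = 0.375))) {
    ll_b <- pdeconf:::cpp_loglik(ob$d, ob$level, ob$a, ob$r, 1,
                                 0.05, 0.6, 0.95, 0.05, 0L, 0, 0, 61L, 61L)
    ll_cb <- pdeconf:::cpp_loglik(ob$d, ob$level, ob$a, ob$r, 1,
                                  0.05, 0.6, 0.95, 0.05, 3L, 0.5, 0, 61L, 61L)
    expect_equal(ll_b, ll_cb, tolerance = 1e-12)
  }
})

test_that("quadrature outcome probabilities match Monte-Carlo frequencies", {
  set.seed(61)
  p <- cb_params(w_bias = 0.7, m = 0.15, mu_low = 0.5, mu_high = 1.0,
                 sigma_report = 0.07)
  op <- outcome_probs(p, d = 1, post_level = "low", n_nodes = 121)
  n <- 5e4
  s <- p$strengths
  x_pre <- rnorm(n, s$mu_low, 1)
  a <- decide(x_pre, p$m)
  x_post <- rnorm(n, s$mu_low, 1)
  conf <- pdeconf:::.confidence_vec(x_pre, x_post, a, p$variant_params,
                                    mixture_moments(s))
  r <- simulate_report(conf, p$sigma_report)
  emp <- as.data.frame(table(action = a, rating = r) / n,
                       stringsAsFactors = FALSE)
  m <- merge(op, emp, all.x = TRUE)
  m$Freq[is.na(m$Freq)] <- 0
  expect_lt(max(abs(m$prob - as.numeric(m$Freq))), 0.012)
})

test_that("subject fits recover generating parameters", {
  set.seed(62)
  tr <- sim_task_trials(cb_params(w_bias = 0.62), n_task1 = 400,
                        n_task2 = 800)
  f <- fit_subject(tr, "choice_bias",
                   config = fit_config(n_nodes_pre = 41, n_nodes_post = 41,
                                       n_restarts = 2))
  expect_equal(f$estimates$w_bias, 0.62, tolerance = 0.08)
  expect_equal(f$estimates$mu_low, 0.6, tolerance = 0.15)
  expect_true(f$estimates$w_bias > 0 && f$estimates$w_bias < 1)
  # data from the base model pull the bias weight back to one half
  set.seed(63)
  tr_b <- sim_task_trials(base_params(), n_task1 = 400, n_task2 = 800)
  f_b <- fit_subject(tr_b, "choice_bias",
                     config = fit_config(n_nodes_pre = 41,
                                         n_nodes_post = 41,
                                         n_restarts = 2))
  expect_equal(f_b$estimates$w_bias, 0.5, tolerance = 0.08)
  expect_error(fit_subject(tr[0, ], "choice_bias"), "empty")
})

test_that("hierarchical fitting shrinks estimates toward the group", {
  set.seed(64)
  trs <- do.call(rbind, lapply(1:6, function(j) {
    tr <- sim_task_trials(cb_params(w_bias = 0.6), n_task1 = 40,
                          n_task2 = 80)
    tr$subject_id <- j
    tr
  }))
  cfg <- fit_config(n_nodes_pre = 41, n_nodes_post = 41, n_restarts = 1,
                    maxit = 300, reltol = 1e-5)
  ind <- fit_population(trs, "choice_bias", config = cfg)
  hier <- fit_population(trs, "choice_bias", hierarchical = TRUE,
                         config = cfg, max_iter = 2)
  wb_i <- vapply(ind$fits, function(f) f$estimates$w_bias, numeric(1))
  wb_h <- vapply(hier$fits, function(f) f$estimates$w_bias, numeric(1))
  expect_lte(var(wb_h), var(wb_i) + 1e-6)
  # single-subject hierarchical request degrades gracefully
  expect_warning(
    fit_population(trs[trs$subject_id == 1, ], "choice_bias",
                   hierarchical = TRUE, config = cfg),
    ">= 2 subjects")
})

test_that("seeded fits are reproducible", {
  set.seed(65)
  tr <- sim_task_trials(cb_params(), n_task1 = 60, n_task2 = 120)
  cfg <- fit_config(n_nodes_pre = 41, n_nodes_post = 41, n_restarts = 2)
  set.seed(66); f1 <- fit_subject(tr, "choice_bias", config = cfg)
  set.seed(66); f2 <- fit_subject(tr, "choice_bias", config = cfg)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("posterior predictive splits a decile and matches well-fit data", {
  set.seed(67)
  # 100 pseudo-fits built from known parameter sets
  fits <- lapply(1:100, function(j) {
    par <- c(0, log(0.6), log(0.35), log(0.04))
    structure(list(subject_id = j, variant = "base", par = par,
                   hessian = NULL,
                   estimates = pdeconf:::.unpack_par(par, "base")),
              class = "fit_result")
  })
  comp <- rnorm(100)
  pp <- posterior_predictive(fits, comp, n_draws = 1, n_trials = 400)
  expect_equal(unique(pp$n_subjects[pp$group == "radical"]), 10)
  expect_equal(unique(pp$n_subjects[pp$group == "moderate"]), 90)
  expect_setequal(unique(pp$condition), c("task1", "low", "high"))
  expect_error(posterior_predictive(fits, comp, n_draws = 0), ">= 1")
  # predictive means match the generating data for a well-fit subject
  set.seed(68)
  tr <- sim_task_trials(cb_params(w_bias = 0.62), n_task1 = 600,
                        n_task2 = 1200, with_calibration = TRUE)
  f <- fit_subject(tr, "choice_bias",
                   config = fit_config(n_nodes_pre = 41, n_nodes_post = 41,
                                       n_restarts = 2))
  pp1 <- posterior_predictive(list(f), 0, n_draws = 20, n_trials = 2000)
  t1 <- tr[tr$phase == "task1" & tr$accuracy == 1, ]
  obs_mean <- mean(t1$confidence)
  pred <- pp1$mean_confidence[pp1$condition == "task1" &
                                pp1$accuracy_class == "correct"]
  expect_equal(pred, obs_mean, tolerance = 0.04)
})
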