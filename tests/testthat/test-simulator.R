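test_that("Weibull sampler has the right special cases and median", {
  set.seed(131)
  n <- 1e5
  x <- rweibull_ph(n, 0.02, 1)          # exponential, mean 50
  expect_lt(abs(mean(x) - 50), 3 * 50 / sqrt(n))
  lam <- log(2) / 365^0.5
  y <- rweibull_ph(n, lam, 0.5)
  expect_equal(median(y), 365, tolerance = 0.03)
  expect_error(rweibull_ph(10, -1, 1))
})

test_that("proportional-hazards structure is recovered from a large two-arm fit", {
  set.seed(137)
  theta <- -0.35
  d <- sim_trial_data(4000, K = 1, theta = theta, median_days = 100,
                      followup = 250)
  fit <- fit_stage1_cox(d)
  expect_equal(fit$theta[1], theta, tolerance = 3 * sqrt(fit$Sigma[1, 1]))
})

test_that("required-events calculator matches the Schoenfeld closed form", {
  expect_identical(required_events(0.80, 0.05, 0.8), 632)
  d <- 4 * (qnorm(0.975) + qnorm(0.8))^2 / log(0.5)^2
  expect_identical(required_events(0.80, 0.05, 0.5), 2 * ceiling(d / 2))
  expect_identical(required_events(0.80, 0.05, 0.5), 66)
  expect_error(required_events(0.80, 0.05, 1), "differ from 1")
})

test_that("degenerate stage 2 designs behave as documented", {
  # no stage-2 patients: the only stage-2 information is carry-over follow-up
  des <- trial_design(K = 2, theta = c(-0.2, 0), control_median = 150,
                      interim_events = 120, stage2_events = 0,
                      stage1_followup = 200,
                      rule = selection_rule("best_loghr"))
  tr <- simulate_trial(des, seed = 3, estimators = "naive")
  j <- tr$outcome$selected
  expect_equal(tr$tau2, tr$tau1)
  ref <- fit_pairwise_cox(tr$data, j, tr$tau1, tr$tau1,
                          stage1_followup = 200)
  expect_equal(tr$summaries$theta_full[j], ref$theta_full, tolerance = 1e-10)
  expect_gt(tr$summaries$V_full[j], tr$summaries$V1[j])

  # no stage-2 events and no carry-over: no increment, informative error
  des0 <- trial_design(K = 2, theta = c(-0.2, 0), control_median = 150,
                       interim_events = 120, stage2_events = 0,
                       stage1_followup = 0,
                       rule = selection_rule("best_loghr"))
  expect_error(simulate_trial(des0, seed = 3, estimators = "naive"),
               "stage-2 information")
})

test_that("replication bookkeeping: single replicate, symmetry, RMSE >= |bias|", {
  des <- trial_design(K = 4, theta = rep(0, 4), interim_events = 150,
                      stage2_events = 60, stage1_followup = 120)
  one <- replicate_trials(des, 1, seed = 5, estimators = "none")
  s <- summary(one)
  expect_true(all(s$selection_prob %in% c(0, 1)))

  rep2 <- replicate_trials(des, 150, seed = 7,
                           estimators = c("naive", "umvcue"))
  s2 <- summary(rep2)
  # equal true effects: selection probabilities agree within binomial error
  se <- 3 * sqrt(0.2 * 0.8 / 150)
  expect_true(all(abs(s2$selection_prob - 0.2) < se + 0.02))
  ok <- !is.na(s2$bias_naive)
  expect_true(all(s2$rmse_naive[ok] >= abs(s2$bias_naive[ok])))
  expect_true(all(s2$rmse_umvcue[ok] >= abs(s2$bias_umvcue[ok])))
  expect_equal(attr(s2, "futility_prob"),
               1 - mean(rowSums(rep2$selected) > 0), tolerance = 1e-12)
})

test_that("continuation probability is monotone in the futility boundary", {
  theta <- rep(0, 4)
  V1 <- rep(75, 4)
  R <- matrix(0.5, 4, 4)
  diag(R) <- 1
  Sigma1 <- R * sqrt((1 / V1) %o% (1 / V1))
  s2 <- rep(1 / 160, 4)
  cont <- vapply(c(-0.2, -0.05, 0, 0.1), function(b) {
    r <- normal_theory_replicates(theta, Sigma1, s2,
                                  selection_rule("best_loghr_le_b", b = b),
                                  n_reps = 2e4, seed = 11,
                                  estimators = "naive")
    mean(!r$futility)
  }, numeric(1))
  expect_true(all(diff(cont) > 0))
})

test_that("selection-free design leaves the naive estimator unbiased", {
  theta <- -0.2
  Sigma1 <- matrix(1 / 80, 1, 1)
  r <- normal_theory_replicates(theta, Sigma1, 1 / 150,
                                selection_rule("best_loghr"),
                                n_reps = 4e4, seed = 13)
  expect_true(all(r$selected[, 1]))   # K = 1, no futility: always selected
  err <- r$naive[, 1] - theta
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
  expect_equal(r$umvcue, r$naive, tolerance = 1e-9)
})

test_that("normal-theory bias-subtracted estimators reduce selection bias", {
  theta <- rep(0, 3)
  V1 <- rep(60, 3)
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  Sigma1 <- R * sqrt((1 / V1) %o% (1 / V1))
  r <- normal_theory_replicates(theta, Sigma1, rep(1 / 120, 3),
                                selection_rule("best_loghr_le_b", b = 0),
                                n_reps = 800, seed = 17,
                                estimators = c("naive", "si", "mi"))
  sel <- r$selected
  naive_bias <- mean(r$naive[sel] - 0)
  si_bias <- mean(r$si[sel] - 0)
  mi_ok <- sel & matrix(r$mi_converged %in% TRUE, nrow(sel), ncol(sel))
  mi_bias <- mean(r$mi[mi_ok] - 0)
  expect_lt(abs(si_bias), abs(naive_bias))
  expect_lt(abs(mi_bias), abs(naive_bias))
})

test_that("trial design validates its inputs", {
  expect_error(trial_design(K = 2, theta = c(0, 0, 0)))
  expect_error(trial_design(gamma = -1))
  d <- trial_design()
  expect_equal(d$lambda0, log(2) / 365^0.5)
  expect_s3_class(d$rule, "selection_rule")
})
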