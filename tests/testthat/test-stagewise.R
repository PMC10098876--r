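test_that("logrank score matches hand-computed hypergeometric sums", {
  d <- toy_logrank_data()
  lr <- logrank_score(d, 1)
  expect_equal(lr$S, -(3 / 6 + 3 / 5 + 3 / 4), tolerance = 1e-12)
  expect_equal(lr$V, 9 / 36 + 6 / 25 + 3 / 16, tolerance = 1e-12)
  expect_equal(lr$theta, lr$S / lr$V)
})

test_that("logrank score is antisymmetric under label swap and errors with no events", {
  set.seed(11)
  d <- sim_trial_data(30, K = 1, theta = -0.4, followup = 120)
  swapped <- d
  swapped$arm <- 1L - swapped$arm
  a <- logrank_score(d, 1)
  b <- logrank_score(swapped, 1)
  expect_equal(a$S, -b$S, tolerance = 1e-10)
  expect_equal(a$V, b$V, tolerance = 1e-10)

  d0 <- d
  d0$event <- 0L
  expect_error(logrank_score(d0, 1), "no events")
})

test_that("stage-1 covariance: single shared control event and experimental-only events", {
  # one control event, four at risk per arm: p_{d,1} = p_{d,2} = 1/2
  n <- 4
  d <- survival_data(data.frame(
    subject_id = 1:12,
    arm = rep(0:2, each = n),
    recruit_time = 0,
    time = c(1, rep(10, n - 1), rep(10, 2 * n)),
    event = c(1, rep(0, n - 1), rep(0, 2 * n))))
  Sig <- stage1_covariance(d)
  s1 <- diag(Sig)
  expect_equal(Sig[1, 2], s1[1] * s1[2] * 0.25, tolerance = 1e-12)

  # every event in an experimental arm: all off-diagonals vanish
  d2 <- survival_data(data.frame(
    subject_id = 1:12,
    arm = rep(0:2, each = n),
    recruit_time = 0,
    time = c(rep(10, n), 1, 2, rep(10, n - 2), 3, rep(10, n - 1)),
    event = c(rep(0, n), 1, 1, rep(0, n - 2), 1, rep(0, n - 1))))
  Sig2 <- stage1_covariance(d2)
  expect_equal(Sig2[1, 2], 0)
})

test_that("shared-control correlation is about one half in a balanced null trial", {
  set.seed(23)
  d <- sim_trial_data(400, K = 2, theta = c(0, 0), followup = 300)
  Sig <- stage1_covariance(d)
  expect_equal(cov2cor(Sig)[1, 2], 0.5, tolerance = 0.05)
})

test_that("stage-1 covariance formula matches Monte-Carlo covariance of the estimates", {
  set.seed(31)
  n_reps <- 400
  th <- matrix(NA_real_, n_reps, 2)
  qhat <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    d <- sim_trial_data(40, K = 2, theta = c(0, 0), followup = 200)
    th[i, 1] <- logrank_score(d, 1)$theta
    th[i, 2] <- logrank_score(d, 2)$theta
    qhat[i] <- stage1_covariance(d)[1, 2]
  }
  emp <- cov(th[, 1], th[, 2])
  # MC standard error of the empirical covariance
  prod_dev <- (th[, 1] - mean(th[, 1])) * (th[, 2] - mean(th[, 2]))
  se <- sd(prod_dev) / sqrt(n_reps)
  expect_lt(abs(emp - mean(qhat)), 3 * se)
  expect_true(all(qhat >= 0))
})

test_that("increment decomposition reproduces the worked-example stage-2 estimate", {
  inc <- increment_decompose(we_theta1[1], we_V1[1], we_theta[1], we_V[1])
  expect_equal(inc$theta2, -0.7701, tolerance = 1e-4)
  expect_equal(inc$sigma2sq, 1 / 8.5555, tolerance = 1e-8)
  expect_equal(inc$t, we_V1[1] / we_V[1])
  expect_error(increment_decompose(0, 5, 0, 4), "V_full > V1")
})

test_that("decompose / recombine is the exact algebraic round trip", {
  set.seed(5)
  for (i in 1:25) {
    th1 <- rnorm(1)
    V1 <- runif(1, 1, 30)
    th <- rnorm(1)
    V <- V1 + runif(1, 0.5, 40)
    inc <- increment_decompose(th1, V1, th, V)
    back <- combine_increments(th1, V1, inc$theta2, inc$sigma2sq)
    expect_equal(back$theta_full, th, tolerance = 1e-12)
    expect_equal(back$V_full, V, tolerance = 1e-12)
    # equal stage estimates: increment equals the common value
    inc2 <- increment_decompose(th, V1, th, V)
    expect_equal(inc2$theta2, th, tolerance = 1e-12)
  }
})

test_that("multi-arm PH fit agrees with the score route near the null and flags separation", {
  set.seed(47)
  d <- sim_trial_data(500, K = 1, theta = 0, followup = 150)
  cox <- fit_stage1_cox(d)
  score <- logrank_score(d, 1)
  expect_lt(abs(cox$theta[1] - score$theta), 0.02)
  expect_true(isSymmetric(cox$Sigma))
  expect_true(all(eigen(cox$Sigma, only.values = TRUE)$values > 0))

  # all-censored experimental arm: monotone partial likelihood
  bad <- d
  bad$event[bad$arm == 1L] <- 0L
  expect_error(fit_stage1_cox(bad), "monotone|singular")
})

test_that("pairwise fit under the two-stage follow-up rule is information-monotone", {
  set.seed(53)
  d <- sim_trial_data(150, K = 2, theta = c(-0.2, 0), median_days = 100,
                      followup = Inf, recruit_span = 200)
  interim <- 150
  f1 <- fit_pairwise_cox(d, 1, interim, interim, stage1_followup = 0)
  f2 <- fit_pairwise_cox(d, 1, interim, 400, stage1_followup = 100)
  f3 <- fit_pairwise_cox(d, 1, interim, 400, stage1_followup = 250)
  expect_gt(f2$V_full, f1$V_full)   # more follow-up, more information
  expect_gt(f3$V_full, f2$V_full)
  # no stage-2 information at all: combined pair equals the stage-1 pair
  z <- fit_pairwise_cox(censor_at(d, interim), 1, interim, interim,
                        stage1_followup = 0)
  expect_equal(z$theta_full, f1$theta_full, tolerance = 1e-10)
  expect_equal(z$V_full, f1$V_full, tolerance = 1e-10)
})

test_that("summaries built from data satisfy the recombination identity", {
  set.seed(61)
  d <- sim_trial_data(120, K = 3, theta = c(-0.3, 0, -0.1),
                      median_days = 120, recruit_span = 250)
  sm <- stage_summaries_from_data(d, selected = c(1L, 3L),
                                  interim_time = 180, analysis_time = 500,
                                  stage1_followup = 150)
  for (j in c(1, 3)) {
    back <- combine_increments(sm$theta1[j], sm$V1[j], sm$theta2[j],
                               sm$sigma2sq[j])
    expect_equal(back$theta_full, sm$theta_full[j], tolerance = 1e-10)
    expect_gt(sm$V_full[j], sm$V1[j])
  }
  expect_true(is.na(sm$theta_full[2]))
  expect_true(is.numeric(sm$theta1_all))
})
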