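test_that("worked example reproduces every published adjusted estimate", {
  fit <- run_worked_example()
  est <- fit$estimates
  expect_equal(est$naive, c(-0.6528, -0.5796))
  expect_equal(est$umvcue, c(-0.6146, -0.5281), tolerance = 2e-3)
  expect_equal(est$si, c(-0.5922, -0.5110), tolerance = 2e-3)
  expect_equal(est$mi, c(-0.5744, -0.4890), tolerance = 2e-3)
  expect_equal(est$shrinkage, c(-0.6754, -0.6057), tolerance = 2e-3)
  expect_true(fit$mi$converged)
  expect_equal(fit$shrinkage$nu2, 0)
  expect_equal(fit$shrinkage$w, 0.5)
  expect_equal(coef(fit, "umvcue"), c(arm1 = -0.6146, arm2 = -0.5281),
               tolerance = 2e-3)
})

test_that("single-arm threshold bias has the univariate truncated-normal closed form", {
  V1 <- 9
  V <- 20
  sm <- stage_summaries(-0.25, V1, -0.3, V)
  rule <- selection_rule("all_loghr_le_b", b = 0)
  out <- apply_rule(rule, sm$theta1, sm$V1)
  theta <- -0.15
  b <- selection_bias(theta, sm, out)
  s1 <- 1 / sqrt(V1)
  alpha <- (0 - theta) / s1
  closed <- (V1 / V) * (-s1 * dnorm(alpha) / pnorm(alpha))
  expect_equal(b[1], closed, tolerance = 1e-6)
})

test_that("an untruncated region yields zero bias, SI = naive, MI in one step", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_loghr_le_b", b = 50)   # never binds
  out <- apply_rule(rule, sm$theta1, sm$V1)
  b <- selection_bias(c(-0.4, -0.5), sm, out)
  expect_equal(b, c(0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(estimate_si(sm, out)), sm$theta_full,
               tolerance = 1e-6)
  mi <- estimate_mi(sm, out)
  expect_true(mi$converged)
  expect_lte(mi$iterations, 2)
  expect_equal(as.numeric(mi$estimates), sm$theta_full, tolerance = 1e-5)
})

test_that("MI fixed point satisfies its defining residual when converged", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_pval_le_a", a = 0.2)
  out <- apply_rule(rule, sm$theta1, sm$V1)
  mi <- estimate_mi(sm, out, tol = 1e-8)
  expect_true(mi$converged)
  naive <- sm$theta_full
  resid <- mi$theta_tilde - (naive - selection_bias(mi$theta_tilde, sm, out))
  expect_lt(max(abs(resid)), 1e-7)
})

test_that("SI corrects towards zero under selection-by-benefit", {
  set.seed(113)
  rule <- selection_rule("best_loghr_le_b", b = 0)
  for (i in 1:8) {
    sm <- random_summaries(3)
    out <- apply_rule(rule, sm$theta1, sm$V1)
    if (out$futility) next
    j <- out$selected
    si <- estimate_si(sm, out)
    expect_gte(as.numeric(si), sm$theta_full[j])
  }
})

test_that("shrinkage limits, convexity and prior-variance estimation behave", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_pval_le_a", a = 0.2)
  out <- apply_rule(rule, sm$theta1, sm$V1)

  sh0 <- estimate_shrinkage(sm, out, w = 0.5, nu2 = 0)
  expect_equal(sh0$stage1, rep(sm$theta1_all, 2))
  expect_equal(as.numeric(sh0$estimates),
               0.5 * sm$theta1_all + 0.5 * sm$theta2[1:2], tolerance = 1e-10)

  shInf <- estimate_shrinkage(sm, out, w = 0.5, nu2 = 1e8)
  expect_equal(shInf$stage1, sm$theta1, tolerance = 1e-5)

  # two-stage value is a convex combination of its two components
  sh <- estimate_shrinkage(sm, out, w = 0.3, nu2 = 0.05)
  for (k in 1:2) {
    lo <- min(sh$stage1[k], sm$theta2[k])
    hi <- max(sh$stage1[k], sm$theta2[k])
    expect_gte(sh$estimates[[k]], lo)
    expect_lte(sh$estimates[[k]], hi)
  }

  # event-count weight: E1 (|S|+1) / (E1 (|S|+1) + E2 (K+1))
  shw <- estimate_shrinkage(sm, out, nu2 = 0, E1 = 717, E2 = 316)
  expect_equal(shw$w, 717 * 3 / (717 * 3 + 316 * 3))

  # dispersed arms give a positive method-of-moments prior variance
  nu2 <- estimate_nu2(c(-1.2, 0.1, 0.8), rep(0.05, 3), -0.1)
  expect_gt(nu2, 0.3)
  expect_equal(estimate_nu2(we_theta1, sm$sigma1sq, sm$theta1_all), 0)
})

test_that("UMVCUE bounds back-map to the selection boundary and vanish when free", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_pval_le_a", a = 0.2)
  out <- apply_rule(rule, sm$theta1, sm$V1)
  for (j in 1:2) {
    b <- umvcue_bounds(sm, out, j)
    expect_identical(b$BU, Inf)
    # the implied stage-1 estimate at theta2 = BL is exactly W_j
    s1 <- sm$sigma1sq[j]
    s2 <- sm$sigma2sq[j]
    th1_at_BL <- ((s1 + s2) * sm$theta_full[j] - s1 * b$BL) / s2
    expect_equal(th1_at_BL, out$W[j], tolerance = 1e-10)
    expect_equal(b$eta, s2 / sqrt(s1 + s2))
  }
  # unbinding threshold: whole-line truncation, UMVCUE = naive
  rule_free <- selection_rule("all_loghr_le_b", b = 100)
  out_free <- apply_rule(rule_free, sm$theta1, sm$V1)
  bf <- umvcue_bounds(sm, out_free, 1)
  expect_equal(umvcue_estimate(sm, out_free, 1, bf), sm$theta_full[1],
               tolerance = 1e-9)
})

test_that("general truncated-mean form equals the one-sided closed form at mapped bounds", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_pval_le_a", a = 0.2)
  out <- apply_rule(rule, sm$theta1, sm$V1)
  for (j in 1:2) {
    s1 <- sm$sigma1sq[j]
    s2 <- sm$sigma2sq[j]
    thj <- sm$theta_full[j]
    eta <- s2 / sqrt(s1 + s2)
    # closed form for an own-threshold rule, as a function of W alone
    g <- (thj - out$W[j]) * sqrt(s1 + s2) / s1
    closed <- thj + eta * dnorm(g) / (1 - pnorm(g))
    expect_equal(umvcue_estimate(sm, out, j), closed, tolerance = 1e-12)
  }
})

test_that("UMVCUE errors on an underflowing two-sided truncation", {
  sm <- worked_example_summaries()
  rule <- selection_rule("all_pval_le_a", a = 0.2)
  out <- apply_rule(rule, sm$theta1, sm$V1)
  bad <- list(BL = 5, BU = 5.01, eta = umvcue_bounds(sm, out, 1)$eta,
              arm = 1L)
  expect_error(umvcue_estimate(sm, out, 1, bad), "underflow")
})

test_that("UMVCUE is conditionally unbiased under the exact normal model (spot check)", {
  theta <- c(-0.1, -0.25, 0)
  V1 <- c(8, 10, 9)
  R <- matrix(0.5, 3, 3)
  diag(R) <- 1
  Sigma1 <- R * sqrt((1 / V1) %o% (1 / V1))
  sigma2sq <- 1 / c(9, 8, 10)
  for (rule in list(selection_rule("best_loghr_le_b", b = 0),
                    selection_rule("all_pval_le_a", a = 0.4))) {
    r <- normal_theory_replicates(theta, Sigma1, sigma2sq, rule,
                                  n_reps = 6e4, seed = 211)
    for (j in 1:3) {
      idx <- r$selected[, j]
      if (sum(idx) < 2000) next
      err <- r$umvcue[idx, j] - theta[j]
      expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
    }
  }
})
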