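# shared fixtures, all generated in code

# 6-subject dataset: 3 control events at t = 1, 2, 3; 3 experimental
# subjects censored at t = 4. Hand-computed logrank sums over the three
# event times (risk sets 3+3, 2+3, 1+3):
#   S = -(3/6 + 3/5 + 3/4) = -1.85
#   V = 9/36 + 6/25 + 3/16 = 0.6775
toy_logrank_data <- function() {
  survival_data(data.frame(
    subject_id = 1:6,
    arm = c(0, 0, 0, 1, 1, 1),
    recruit_time = 0,
    time = c(1, 2, 3, 4, 4, 4),
    event = c(1, 1, 1, 0, 0, 0)))
}

# balanced (K+1)-arm trial with exponential event times and staggered
# recruitment; all subjects followed to `followup` days on study
sim_trial_data <- function(n_per_arm, K = 2, theta = rep(0, K),
                           median_days = 100, followup = Inf,
                           recruit_span = 50) {
  lam <- log(2) / median_days * exp(c(0, theta))
  arm <- rep(0:K, each = n_per_arm)
  n <- length(arm)
  tt <- rweibull_ph(n, 1, 1) / lam[arm + 1]
  ev <- rep(1L, n)
  if (is.finite(followup)) {
    ev[tt > followup] <- 0L
    tt <- pmin(tt, followup)
  }
  survival_data(data.frame(
    subject_id = seq_len(n), arm = arm,
    recruit_time = runif(n, 0, recruit_span),
    time = tt, event = ev))
}

# random valid stage summaries for property tests
random_summaries <- function(K = 3) {
  V1 <- runif(K, 4, 20)
  R <- matrix(0.5, K, K)
  diag(R) <- 1
  s1 <- 1 / V1
  Sigma1 <- R * sqrt(s1 %o% s1)
  theta1 <- rnorm(K, -0.3, 0.3)
  V_full <- V1 + runif(K, 2, 15)
  theta_full <- rnorm(K, theta1, 0.1)
  stage_summaries(theta1, V1, theta_full, V_full, Sigma1 = Sigma1)
}

# worked-example summary constants, used across files
we_theta1 <- c(-0.5284, -0.5327)
we_V1 <- c(8.0705, 8.7239)
we_theta <- c(-0.6528, -0.5796)
we_V <- c(16.6260, 16.7495)
we_q12 <- 0.0522
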