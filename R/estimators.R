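#' Selection bias of the naive estimators under a working truth
#'
#' For a working vector `theta` of true log hazard ratios, computes the bias
#' vector of the naive estimators induced by interim selection: for a
#' selected arm j the naive estimator is the combined-data estimate, whose
#' bias is `t_j * (E[theta1_j 1_S] / Prob(S) - theta_j)` with information
#' fraction `t_j = V1_j / V_j`; for an unselected arm the naive estimator is
#' the stage-1 estimate, with bias `E[theta1_j 1_S] / Prob(S) - theta_j`.
#'
#' @param theta K-vector of working true effects.
#' @param summaries a [stage_summaries] object.
#' @param outcome a `selection_outcome` from [apply_rule].
#' @return K-vector of biases.
#' @export
selection_bias <- function(theta, summaries, outcome) {
  sm <- selection_moments(theta, summaries$Sigma1, outcome)
  cond <- sm$moments / sm$prob
  wgt <- rep(1, summaries$K)
  wgt[outcome$selected] <- summaries$t[outcome$selected]
  wgt * (cond - theta)
}

# naive working vector: combined estimate for selected arms, stage-1
# estimate for the rest
.naive_vector <- function(summaries, outcome) {
  th <- summaries$theta1
  th[outcome$selected] <- summaries$theta_full[outcome$selected]
  th
}

#' Single-iteration bias-subtracted estimator
#'
#' Evaluates the selection bias at the naive estimates themselves and
#' subtracts it: `theta_SI_j = theta_hat_j - b_j(theta_hat)`.
#'
#' @inheritParams selection_bias
#' @return named vector of estimates for the selected arms.
#' @export
estimate_si <- function(summaries, outcome) {
  th <- .naive_vector(summaries, outcome)
  b <- selection_bias(th, summaries, outcome)
  setNames((th - b)[outcome$selected], paste0("arm", outcome$selected))
}

#' Multiple-iterations bias-subtracted estimator
#'
#' Solves the bias fixed point `theta_tilde = theta_hat - b(theta_tilde)` by
#' functional iteration started at the naive vector, then reports
#' `theta_hat_j - b_j(theta_tilde)` for the selected arms. Convergence is
#' declared when the sup-norm step falls below `tol`; divergence (step norm
#' doubling over 10 consecutive iterations) or hitting `max_iter` returns
#' the last iterate with `converged = FALSE` rather than an error, so a
#' prespecified fallback estimator can be used.
#'
#' @inheritParams selection_bias
#' @param tol sup-norm step tolerance for the fixed point.
#' @param max_iter maximum number of iterations.
#' @return list with `estimates` (selected arms), `converged`, `iterations`
#'   and the fixed point `theta_tilde`.
#' @export
estimate_mi <- function(summaries, outcome, tol = 1e-6, max_iter = 100) {
  th <- .naive_vector(summaries, outcome)
  tilde <- th
  converged <- FALSE
  last_step <- Inf
  grow <- 0L
  iter <- 0L
  b <- selection_bias(tilde, summaries, outcome)
  while (iter < max_iter) {
    iter <- iter + 1L
    new <- th - b
    step <- max(abs(new - tilde))
    tilde <- new
    b <- selection_bias(tilde, summaries, outcome)
    if (step <= tol) {
      converged <- TRUE
      break
    }
    grow <- if (step > 2 * last_step) grow + 1L else 0L
    if (grow >= 10L) break
    last_step <- step
  }
  list(estimates = setNames((th - b)[outcome$selected],
                            paste0("arm", outcome$selected)),
       converged = converged, iterations = iter, theta_tilde = tilde)
}

#' Method-of-moments estimate of the prior variance for shrinkage
#'
#' Fixed-point iteration for the between-arm prior variance `nu2` of the
#' empirical-Bayes shrinkage estimator:
#' `nu2 <- max(0, sum(w_j ((theta1_j - theta1_all)^2 - sigma1sq_j)) / sum(w_j))`
#' with precision weights `w_j = 1 / (nu2 + sigma1sq_j)`, iterated to
#' convergence. Truncation at zero corresponds to complete shrinkage to the
#' pooled estimate.
#'
#' @param theta1 stage-1 estimates.
#' @param sigma1sq their variances.
#' @param theta1_all pooled stage-1 estimate (shrinkage target).
#' @param tol convergence tolerance.
#' @param max_iter maximum iterations.
#' @return the estimated `nu2` (scalar, >= 0).
#' @export
estimate_nu2 <- function(theta1, sigma1sq, theta1_all, tol = 1e-8,
                         max_iter = 1000) {
  d2 <- (theta1 - theta1_all)^2
  nu2 <- max(0, mean(d2 - sigma1sq))
  for (i in seq_len(max_iter)) {
    w <- 1 / (nu2 + sigma1sq)
    new <- max(0, sum(w * (d2 - sigma1sq)) / sum(w))
    if (abs(new - nu2) <= tol) return(new)
    nu2 <- new
  }
  stop("nu2 estimation did not converge; supply nu2 explicitly ",
       "(nu2 = 0 corresponds to complete shrinkage)", call. = FALSE)
}

#' Two-stage empirical-Bayes shrinkage estimator
#'
#' Shrinks the stage-1 estimates towards the pooled stage-1 estimate using
#' the posterior-mean matrix
#' `C = I - Sigma1 %*% solve(nu2 * I + Sigma1)`, then combines with the
#' independent stage-2 increment:
#' `theta_SH_j = w * (C theta1 + (I - C) theta1_all)_j + (1 - w) * theta2_j`.
#' With `nu2 = 0` the stage-1 component equals `theta1_all` for every arm
#' (complete shrinkage); as `nu2 -> Inf` it tends to the raw `theta1`.
#'
#' @inheritParams selection_bias
#' @param w weight in `[0, 1]` on the stage-1 shrinkage component. When `E1`
#'   and `E2` (planned events at the interim and from stage-2 patients) are
#'   supplied, the default is `E1 (|S|+1) / (E1 (|S|+1) + E2 (K+1))`.
#' @param nu2 prior variance, or `"estimate"` to use [estimate_nu2].
#' @param theta1_all pooled stage-1 estimate; defaults to the one stored in
#'   `summaries`.
#' @param E1,E2 optional planned event counts driving the default weight.
#' @return list with `estimates` (selected arms), `stage1` (the K-vector of
#'   stage-1 shrinkage values), `nu2` and `w`.
#' @export
estimate_shrinkage <- function(summaries, outcome, w = 0.5,
                               nu2 = "estimate", theta1_all = NULL,
                               E1 = NULL, E2 = NULL) {
  if (is.null(theta1_all)) theta1_all <- summaries$theta1_all
  if (is.null(theta1_all)) {
    stop("theta1_all (pooled stage-1 estimate) must be supplied when not ",
         "available in the summaries", call. = FALSE)
  }
  if (identical(nu2, "estimate")) {
    nu2 <- estimate_nu2(summaries$theta1, summaries$sigma1sq, theta1_all)
  }
  stopifnot(is.numeric(nu2), nu2 >= 0)
  if (!is.null(E1) && !is.null(E2)) {
    S1 <- length(outcome$selected)
    w <- E1 * (S1 + 1) / (E1 * (S1 + 1) + E2 * (summaries$K + 1))
  }
  stopifnot(w >= 0, w <= 1)
  K <- summaries$K
  C <- diag(K) - summaries$Sigma1 %*% solve(nu2 * diag(K) + summaries$Sigma1)
  sh1 <- as.numeric(C %*% summaries$theta1 +
                    (diag(K) - C) %*% rep(theta1_all, K))
  est <- w * sh1[outcome$selected] +
    (1 - w) * summaries$theta2[outcome$selected]
  list(estimates = setNames(est, paste0("arm", outcome$selected)),
       stage1 = sh1, nu2 = nu2, w = w)
}

#' Truncation bounds of the stage-2 estimate for the UMVCUE
#'
#' Maps the interim selection constraints on the stage-1 estimates to bounds
#' `(BL, BU)` on the stage-2 increment estimate `theta2_j`, holding the
#' complete sufficient statistic fixed. Each active constraint (the arm's
#' own efficacy/futility threshold, and — for best-type rules — each
#' competitor comparison) is linear in `theta2_j` given the sufficient
#' statistic; a constraint whose coefficient is positive contributes a lower
#' bound and one with a negative coefficient an upper bound (the sign is
#' that of `sigma1_j^2 - q_jl` on the log HR scale, or of
#' `sigma1_j sigma1_l - q_jl` on the p-value scale). The truncation interval
#' is the intersection of all contributions; a constraint with zero
#' coefficient does not involve `theta2_j` and imposes no bound. For
#' threshold ("all"-type) rules only the arm's own bound applies and
#' `BU = +Inf`.
#'
#' @inheritParams selection_bias
#' @param arm a selected arm index.
#' @return list with `BL`, `BU`, `eta` (= `sigma2sq / sqrt(sigma1sq +
#'   sigma2sq)`) and `arm`.
#' @export
umvcue_bounds <- function(summaries, outcome, arm) {
  j <- arm
  if (!j %in% outcome$selected) stop("arm ", j, " was not selected",
                                     call. = FALSE)
  s1 <- summaries$sigma1sq[j]
  s2 <- summaries$sigma2sq[j]
  if (is.na(s2)) stop("arm ", j, " has no stage-2 increment", call. = FALSE)
  t2o <- summaries$theta2[j]
  th1 <- outcome$theta1
  V1 <- outcome$V1
  rule <- outcome$rule
  BL <- -Inf
  BU <- Inf
  u <- .rule_threshold(rule, V1)[j]
  if (is.finite(u)) {
    BL <- max(BL, t2o - s2 * (u - th1[j]) / s1)
  }
  if (rule$type == "best") {
    for (l in setdiff(seq_len(summaries$K), j)) {
      qjl <- summaries$Sigma1[j, l]
      if (rule$scale == "loghr") {
        d <- s1 - qjl
        slack <- th1[l] - th1[j]
      } else {
        d <- s1 - qjl * sqrt(V1[l] / V1[j])
        slack <- th1[l] * sqrt(V1[l] / V1[j]) - th1[j]
      }
      if (abs(d) < 1e-14 * s1) next  # constraint free of theta2_j
      bound <- t2o - s2 * slack / d
      if (d > 0) BL <- max(BL, bound) else BU <- min(BU, bound)
    }
  }
  list(BL = BL, BU = BU, eta = s2 / sqrt(s1 + s2), arm = j)
}

#' Approximate uniformly minimum variance conditional unbiased estimator
#'
#' Rao-Blackwell-type estimator for a selected arm: the conditional mean of
#' the unbiased stage-2 increment given the complete sufficient statistic
#' and the selection event, which is a normal mean truncated to
#' `(BL, BU)`:
#' `theta_UMV = theta_hat_j - eta * (phi(u) - phi(l)) / (Phi(u) - Phi(l))`
#' with `u = (BU - theta_hat_j)/eta`, `l = (BL - theta_hat_j)/eta`.
#' One-sided truncations are evaluated on the log scale (Mills ratio) for
#' numerical stability in the tails.
#'
#' @inheritParams selection_bias
#' @param arm a selected arm index.
#' @param bounds optional [umvcue_bounds] result (recomputed if omitted).
#' @return the UMVCUE estimate (scalar).
#' @export
umvcue_estimate <- function(summaries, outcome, arm, bounds = NULL) {
  if (is.null(bounds)) bounds <- umvcue_bounds(summaries, outcome, arm)
  thj <- summaries$theta_full[bounds$arm]
  eta <- bounds$eta
  l <- (bounds$BL - thj) / eta
  u <- (bounds$BU - thj) / eta
  if (!is.finite(l) && !is.finite(u)) return(thj)
  if (!is.finite(u)) {          # lower truncation only: + eta * phi/(1-Phi)
    return(thj + eta * exp(dnorm(l, log = TRUE) -
                           pnorm(l, lower.tail = FALSE, log.p = TRUE)))
  }
  if (!is.finite(l)) {          # upper truncation only: - eta * phi/Phi
    return(thj - eta * exp(dnorm(u, log = TRUE) -
                           pnorm(u, log.p = TRUE)))
  }
  denom <- pnorm(u) - pnorm(l)
  if (denom < .PROB_FLOOR) {
    stop(sprintf(paste0("Phi-difference underflow for arm %d on bounds ",
                        "(%.4g, %.4g): truncated mean not computable"),
                 bounds$arm, bounds$BL, bounds$BU), call. = FALSE)
  }
  thj - eta * (dnorm(u) - dnorm(l)) / denom
}
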