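#' Logrank score statistic and Fisher information for one pairwise comparison
#'
#' Computes the logrank (partial-likelihood score at beta = 0) statistic `S`
#' and the hypergeometric Fisher information `V` comparing one experimental
#' arm to the control, with administrative censoring applied at
#' `analysis_time` on the calendar scale. The log hazard ratio estimate is
#' `S/V`; the sign convention is that negative values favour the experimental
#' arm. Asymptotically `S ~ N(theta * V, V)`.
#'
#' Tied event times are handled by the Breslow convention: each tied event
#' contributes its own observed-minus-expected term with the risk set held
#' fixed at the tie time.
#'
#' @param data a [survival_data] object.
#' @param arm experimental arm index in `1..K`.
#' @param analysis_time calendar time of the data freeze.
#' @return list with elements `S`, `V` and `theta = S/V`.
#' @export
logrank_score <- function(data, arm, analysis_time = Inf) {
  stopifnot(arm >= 1, arm <= n_arms(data))
  d <- censor_at(data[data$arm %in% c(0L, arm), , drop = FALSE], analysis_time)
  if (!nrow(d) || sum(d$event) == 0L) {
    stop("log hazard ratio not estimable: no events (V = 0)", call. = FALSE)
  }
  z <- as.integer(d$arm == arm)
  ev_times <- sort(unique(d$time[d$event == 1L]))
  S <- 0
  V <- 0
  for (t in ev_times) {
    at_risk <- d$time >= t
    r1 <- sum(z[at_risk])
    r <- sum(at_risk)
    r0 <- r - r1
    if (r1 == 0L || r0 == 0L) next
    ev <- d$event == 1L & d$time == t
    dn <- sum(ev)
    S <- S + sum(z[ev]) - dn * r1 / r
    V <- V + dn * r1 * r0 / r^2
  }
  if (V <= 0) {
    stop("log hazard ratio not estimable: no at-risk overlap (V = 0)",
         call. = FALSE)
  }
  list(S = S, V = V, theta = S / V)
}

#' Covariance matrix of stage-1 log hazard ratio estimates
#'
#' Stage-1 log hazard ratio estimates for different experimental arms are
#' correlated because they share the control arm. For arms i and j, the
#' covariance is
#' `q_ij = sigma1_i^2 * sigma1_j^2 * sum_d p_{d,i} p_{d,j}`,
#' where the sum runs over the stage-1 event times of the control and the two
#' arms, `p_{d,i} = r_{d,i} / (r_{d,c} + r_{d,i})` if the event at `t_d`
#' occurred in the control or in arm i, and 0 if it occurred in the other
#' experimental arm. Only control-arm events contribute a nonzero product.
#' Tied event times are processed as simultaneous events with risk sets fixed
#' at the tie time, summing their p-products.
#'
#' @inheritParams logrank_score
#' @return K x K symmetric covariance matrix with diagonal `1/V1_j`.
#' @export
stage1_covariance <- function(data, analysis_time = Inf) {
  K <- n_arms(data)
  stopifnot(K >= 1)
  d <- censor_at(data, analysis_time)
  V1 <- numeric(K)
  for (j in seq_len(K)) {
    V1[j] <- logrank_score(d, j)$V   # errors if non-estimable
  }
  Sigma <- diag(1 / V1, K)
  if (K >= 2) {
    for (i in seq_len(K - 1L)) {
      for (j in seq.int(i + 1L, K)) {
        dd <- d[d$arm %in% c(0L, i, j), , drop = FALSE]
        ctrl_ev <- dd$time[dd$event == 1L & dd$arm == 0L]
        ssum <- 0
        for (t in ctrl_ev) {
          at <- dd$time >= t
          rc <- sum(at & dd$arm == 0L)
          ri <- sum(at & dd$arm == i)
          rj <- sum(at & dd$arm == j)
          ssum <- ssum + (ri / (rc + ri)) * (rj / (rc + rj))
        }
        Sigma[i, j] <- Sigma[j, i] <- ssum / (V1[i] * V1[j])
      }
    }
  }
  Sigma
}

.check_cox_fit <- function(fit, context) {
  beta <- coef(fit)
  vc <- vcov(fit)
  if (any(!is.finite(beta)) || any(!is.finite(vc)) ||
      any(abs(beta) > 15) || any(diag(vc) > 1e4)) {
    stop(sprintf(paste0(
      "%s: partial likelihood is monotone or information is singular ",
      "(separation / no events in an arm); estimates not identifiable"),
      context), call. = FALSE)
  }
  invisible(fit)
}

#' Stage-1 multi-arm proportional hazards fit
#'
#' Fits a single Cox proportional hazards model with K treatment-indicator
#' covariates to all stage-1 data (administratively censored at
#' `analysis_time`), returning the vector of stage-1 log hazard ratio
#' estimates and the full estimated covariance matrix, whose off-diagonal
#' entries capture the shared-control correlation. Ties use the Breslow
#' convention.
#'
#' @inheritParams logrank_score
#' @return list with `theta` (K-vector), `Sigma` (K x K covariance),
#'   `V1 = 1/diag(Sigma)`.
#' @export
fit_stage1_cox <- function(data, analysis_time = Inf) {
  K <- n_arms(data)
  d <- censor_at(data, analysis_time)
  if (sum(d$event) == 0L) stop("no events: stage-1 model not estimable",
                               call. = FALSE)
  arm_f <- factor(d$arm, levels = 0:K)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(d$time, d$event) ~ arm_f,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)))
  .check_cox_fit(fit, "stage-1 model")
  Sigma <- unname(vcov(fit))
  Sigma <- (Sigma + t(Sigma)) / 2
  list(theta = unname(coef(fit)), Sigma = Sigma, V1 = 1 / diag(Sigma))
}

#' Combined-data pairwise proportional hazards fit
#'
#' Fits the stage-2 model for one selected arm: a Cox model on the control
#' and that arm only, using all stage-1 data plus stage-2 data. Follow-up is
#' truncated by the prefixed rule that preserves the approximate
#' independent-increment structure: stage-1 patients (recruited before
#' `interim_time`) are censored at `interim_time + stage1_followup`, and
#' stage-2 patients at `analysis_time`.
#'
#' @inheritParams logrank_score
#' @param interim_time calendar time of the interim data freeze.
#' @param analysis_time calendar censoring time for stage-2 patients.
#' @param stage1_followup days of additional stage-2 follow-up of stage-1
#'   patients without events at the interim (`Inf` = follow to
#'   `analysis_time`).
#' @param route `"cox"` (partial-likelihood fit) or `"score"` (logrank
#'   score statistic).
#' @return list with `theta_full` and `V_full` for the comparison.
#' @export
fit_pairwise_cox <- function(data, arm, interim_time, analysis_time,
                             stage1_followup = Inf, route = c("cox", "score")) {
  route <- match.arg(route)
  d <- .two_stage_censor(data, arm, interim_time, analysis_time,
                         stage1_followup)
  if (route == "score") {
    lr <- logrank_score(d, 1L)
    return(list(theta_full = lr$theta, V_full = lr$V))
  }
  if (sum(d$event) == 0L) stop("no events: stage-2 model not estimable",
                               call. = FALSE)
  z <- as.integer(d$arm == 1L)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(d$time, d$event) ~ z,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)))
  .check_cox_fit(fit, sprintf("stage-2 model (arm %d)", arm))
  list(theta_full = unname(coef(fit)), V_full = 1 / unname(vcov(fit)[1, 1]))
}

# restrict to control + one arm, apply the per-cohort censoring rule, and
# recode the arm to 1 so downstream code sees a two-arm dataset
.two_stage_censor <- function(data, arm, interim_time, analysis_time,
                              stage1_followup) {
  d <- data[data$arm %in% c(0L, arm), , drop = FALSE]
  s1 <- d$recruit_time < interim_time
  cut <- ifelse(s1, interim_time + stage1_followup, analysis_time)
  keep <- d$recruit_time < cut
  d <- d[keep, , drop = FALSE]
  cut <- cut[keep]
  cal <- d$recruit_time + d$time
  over <- cal > cut
  d$time[over] <- cut[over] - d$recruit_time[over]
  d$event[over] <- 0L
  d$arm <- as.integer(d$arm == arm)
  class(d) <- c("survival_data", "data.frame")
  d
}

#' Pooled stage-1 comparison of control versus all experimental arms
#'
#' Treats the K experimental arms as a single treatment and estimates one log
#' hazard ratio against the control from stage-1 data; used as the shrinkage
#' target.
#'
#' @inheritParams logrank_score
#' @inheritParams fit_pairwise_cox
#' @return the pooled log hazard ratio estimate (scalar).
#' @export
fit_pooled_stage1 <- function(data, analysis_time = Inf,
                              route = c("cox", "score")) {
  route <- match.arg(route)
  d <- censor_at(data, analysis_time)
  d$arm <- as.integer(d$arm > 0L)
  class(d) <- c("survival_data", "data.frame")
  if (route == "score") return(logrank_score(d, 1L)$theta)
  z <- d$arm
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(d$time, d$event) ~ z, ties = "breslow"))
  .check_cox_fit(fit, "pooled stage-1 model")
  unname(coef(fit))
}

#' Independent-increment decomposition of a combined estimate
#'
#' Converts a stage-1 estimate and a combined (stage 1 + stage 2) estimate
#' into the approximately independent stage-2 increment on the score scale:
#' with `S1 = theta1 * V1` and `S = theta_full * V_full`,
#' `theta2 = (S - S1) / (V_full - V1)` and `sigma2sq = 1 / (V_full - V1)`.
#' [combine_increments] is the exact algebraic inverse (the
#' inverse-variance-weighted recombination identity).
#'
#' @param theta1,V1 stage-1 log hazard ratio estimate(s) and Fisher
#'   information(s).
#' @param theta_full,V_full combined-data estimate(s) and information(s).
#' @return list with `theta2`, `sigma2sq` and the information fraction
#'   `t = V1/V_full` (vectorized).
#' @export
increment_decompose <- function(theta1, V1, theta_full, V_full) {
  if (any(V1 <= 0) || any(V_full <= V1)) {
    stop("no stage-2 information: require V_full > V1 > 0", call. = FALSE)
  }
  V2 <- V_full - V1
  list(theta2 = (theta_full * V_full - theta1 * V1) / V2,
       sigma2sq = 1 / V2,
       t = V1 / V_full)
}

#' @rdname increment_decompose
#' @param theta2,sigma2sq stage-2 increment estimate(s) and variance(s).
#' @export
combine_increments <- function(theta1, V1, theta2, sigma2sq) {
  s1 <- 1 / V1
  theta_full <- (sigma2sq * theta1 + s1 * theta2) / (s1 + sigma2sq)
  list(theta_full = theta_full, V_full = V1 + 1 / sigma2sq)
}
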