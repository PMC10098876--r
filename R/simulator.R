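#' Weibull event times under proportional hazards
#'
#' Samples event times with survival function `exp(-lambda * t^gamma)`
#' (hazard `lambda * gamma * t^(gamma - 1)`). An arm with log hazard ratio
#' `theta` against a control with scale `lambda0` uses
#' `lambda = exp(theta) * lambda0`. The median is `(log(2)/lambda)^(1/gamma)`.
#'
#' @param n number of samples.
#' @param lambda Weibull scale (> 0) on the cumulative-hazard
#'   parameterization `H(t) = lambda * t^gamma`.
#' @param gamma Weibull shape (> 0); `gamma = 1` is the exponential.
#' @return vector of event times.
#' @export
rweibull_ph <- function(n, lambda, gamma) {
  stopifnot(lambda > 0, gamma > 0)
  (-log(runif(n)) / lambda)^(1 / gamma)
}

#' Two-stage multi-arm trial design
#'
#' Describes a seamless phase II/III design with proportional Weibull
#' hazards: K experimental arms plus control, uniform recruitment, an
#' interim analysis triggered by a prefixed total event count, stage-2
#' follow-up stopped at a prefixed event count from stage-2 patients, and a
#' prefixed calendar extension of follow-up for stage-1 patients without
#' events at the interim (which preserves the approximate
#' independent-increment structure). Defaults reproduce the reference
#' operating-characteristics study: K = 4, shape 0.5, control median 365
#' days, 1 recruit/day, interim at 717 deaths, 316 stage-2 deaths, 1-year
#' carry-over follow-up, select-the-best rule with futility boundary 0.
#'
#' @param K number of experimental arms.
#' @param theta K-vector of true log hazard ratios.
#' @param gamma Weibull shape of all hazards.
#' @param control_median control median survival in days; the control scale
#'   is `lambda0 = log(2) / control_median^gamma`.
#' @param recruit_rate subjects per day (uniform arrivals).
#' @param interim_events total deaths (all arms) triggering the interim.
#' @param stage2_events deaths from stage-2 patients triggering the end of
#'   stage-2 follow-up.
#' @param stage1_followup days of stage-2 follow-up of stage-1 patients
#'   without events at the interim.
#' @param rule a [selection_rule].
#' @param route estimation route, `"cox"` or `"score"`.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(K = 4, theta = rep(0, K), gamma = 0.5,
                         control_median = 365, recruit_rate = 1,
                         interim_events = 717, stage2_events = 316,
                         stage1_followup = 365,
                         rule = selection_rule("best_loghr_le_b", b = 0),
                         route = c("cox", "score")) {
  route <- match.arg(route)
  stopifnot(K >= 1, length(theta) == K, gamma > 0, control_median > 0,
            recruit_rate > 0, interim_events >= 1, stage2_events >= 0,
            stage1_followup >= 0, inherits(rule, "selection_rule"))
  structure(list(K = K, theta = theta, gamma = gamma,
                 control_median = control_median,
                 lambda0 = log(2) / control_median^gamma,
                 recruit_rate = recruit_rate,
                 interim_events = interim_events,
                 stage2_events = stage2_events,
                 stage1_followup = stage1_followup,
                 rule = rule, route = route),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(paste0("Two-stage trial design: K = %d arms, Weibull shape ",
                     "%.3g, control median %.4g d\n"),
              x$K, x$gamma, x$control_median))
  cat(sprintf("  theta = (%s)\n", paste(format(x$theta), collapse = ", ")))
  cat(sprintf(paste0("  %.3g recruit(s)/day; interim at %d deaths; %d ",
                     "stage-2 deaths; carry-over follow-up %.4g d\n"),
              x$recruit_rate, x$interim_events, x$stage2_events,
              x$stage1_followup))
  print(x$rule)
  invisible(x)
}

# blocked 1:1:...:1 allocation over the given arm codes
.blocked_alloc <- function(n, arms) {
  nb <- ceiling(n / length(arms))
  out <- unlist(lapply(seq_len(nb), function(i) sample(arms)))
  out[seq_len(n)]
}

# recruit at fixed rate starting after `from` and sample latent event times;
# extends the horizon until the `n_events`-th calendar death is within it
# (later recruits cannot precede it), then returns the cohort and trigger time
.recruit_until <- function(design, arms, from, n_events, lambda_by_arm) {
  rate <- design$recruit_rate
  horizon <- from + max(2 * n_events / rate, 200)
  repeat {
    n <- floor((horizon - from) * rate)
    arm <- .blocked_alloc(n, arms)
    rec <- from + seq_len(n) / rate
    tt <- rweibull_ph(n, 1, design$gamma) / lambda_by_arm[arm + 1L]^(1 / design$gamma)
    cal <- rec + tt
    scal <- sort(cal)
    if (length(scal) >= n_events && scal[n_events] <= horizon) {
      return(list(arm = arm, rec = rec, cal = cal,
                  trigger = scal[n_events]))
    }
    horizon <- from + 2 * (horizon - from)
  }
}

#' Simulate one two-stage trial
#'
#' Recruits continuously, freezes stage-1 data when the interim event count
#' is reached, applies the selection rule, and — unless the trial stops for
#' futility — restricts stage-2 allocation to the control and selected arms,
#' stops stage-2 follow-up at its event trigger, censors stage-1 carry-over
#' patients at interim + `stage1_followup`, and computes the requested
#' estimators.
#'
#' @param design a [trial_design].
#' @param seed optional integer seed.
#' @param estimators character vector among `"naive"`, `"umvcue"`, `"si"`,
#'   `"mi"`, `"shrinkage"`, or `"none"` to stop after selection (no stage-2
#'   simulation).
#' @return list of class `seamtte_trial` with elements `outcome`, `tau1`,
#'   `tau2`, `data` (latent per-subject records, all events observed),
#'   `summaries`, `fit` (a [selest] object, or `NULL`), `theta1`, `V1`.
#' @export
simulate_trial <- function(design, seed = NULL,
                           estimators = c("naive", "umvcue", "si", "mi",
                                          "shrinkage")) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  K <- design$K
  lam <- design$lambda0 * exp(c(0, design$theta))
  ## stage 1: all arms until the interim trigger
  s1 <- .recruit_until(design, 0:K, 0, design$interim_events, lam)
  tau1 <- s1$trigger
  keep <- s1$rec < tau1
  d1 <- data.frame(subject_id = seq_len(sum(keep)),
                   arm = s1$arm[keep], recruit_time = s1$rec[keep],
                   time = s1$cal[keep] - s1$rec[keep],
                   event = 1L)
  d1 <- survival_data(d1)
  if (design$route == "cox") {
    f1 <- fit_stage1_cox(d1, tau1)
    theta1 <- f1$theta
    V1 <- f1$V1
    Sigma1 <- f1$Sigma
  } else {
    theta1 <- V1 <- numeric(K)
    for (j in seq_len(K)) {
      lr <- logrank_score(d1, j, tau1)
      theta1[j] <- lr$theta
      V1[j] <- lr$V
    }
    Sigma1 <- NULL
  }
  outcome <- apply_rule(design$rule, theta1, V1)
  res <- structure(list(outcome = outcome, tau1 = tau1, tau2 = NA_real_,
                        data = d1, summaries = NULL, fit = NULL,
                        theta1 = theta1, V1 = V1, design = design),
                   class = "seamtte_trial")
  if (outcome$futility || identical(estimators, "none")) return(res)
  ## stage 2: control + selected arms only
  sel <- outcome$selected
  if (design$stage2_events > 0) {
    s2 <- .recruit_until(design, c(0L, sel), tau1, design$stage2_events, lam)
    tau2 <- s2$trigger
    keep2 <- s2$rec < tau2
    d2 <- data.frame(subject_id = nrow(d1) + seq_len(sum(keep2)),
                     arm = s2$arm[keep2], recruit_time = s2$rec[keep2],
                     time = s2$cal[keep2] - s2$rec[keep2],
                     event = 1L)
    data <- survival_data(rbind(as.data.frame(d1), d2))
  } else {
    tau2 <- tau1
    data <- d1
  }
  res$tau2 <- tau2
  res$data <- data
  theta_full <- V_full <- rep(NA_real_, K)
  for (j in sel) {
    fit <- fit_pairwise_cox(data, j, tau1, tau2, design$stage1_followup,
                            design$route)
    theta_full[j] <- fit$theta_full
    V_full[j] <- fit$V_full
  }
  if (design$route == "score") Sigma1 <- stage1_covariance(d1, tau1)
  theta1_all <- if ("shrinkage" %in% estimators) {
    fit_pooled_stage1(d1, tau1, design$route)
  }
  summaries <- stage_summaries(theta1, V1, theta_full, V_full,
                               Sigma1 = Sigma1, theta1_all = theta1_all)
  res$summaries <- summaries
  if (identical(estimators, "naive")) {
    res$fit <- structure(list(summaries = summaries, rule = design$rule,
                              outcome = outcome,
                              estimates = data.frame(
                                arm = sel, naive = theta_full[sel]),
                              mi = NULL, shrinkage = NULL, bounds = NULL),
                         class = "selest")
    return(res)
  }
  if (all(c("si", "mi", "shrinkage") %in% estimators)) {
    res$fit <- selest(summaries, design$rule, outcome = outcome,
                      E1 = design$interim_events, E2 = design$stage2_events)
  } else {
    est <- data.frame(arm = sel, naive = theta_full[sel])
    if ("umvcue" %in% estimators) {
      est$umvcue <- vapply(sel, function(j)
        umvcue_estimate(summaries, outcome, j), numeric(1))
    }
    res$fit <- structure(list(summaries = summaries, rule = design$rule,
                              outcome = outcome, estimates = est,
                              mi = NULL, shrinkage = NULL, bounds = NULL),
                         class = "selest")
  }
  res
}

#' Replicate a design and summarize operating characteristics
#'
#' Simulates `n_reps` independent trials (one RNG substream per replicate)
#' and reports per-arm selection frequencies, the futility frequency, and —
#' conditional on each arm being selected — the bias and root mean squared
#' error of each requested estimator. Replicates where the multiple-
#' iterations fixed point fails to converge are excluded from the MI metrics
#' and counted; per-replicate estimation errors are recorded, not raised.
#'
#' @inheritParams simulate_trial
#' @param n_reps number of simulated trials.
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @return an object of class `trial_replicates`: list with `selected`
#'   (n_reps-vector, 0 = futility), `estimates` (list of n_reps x K matrices
#'   per estimator), `mi_converged`, `n_errors`, `design`, `seed`.
#' @export
replicate_trials <- function(design, n_reps, seed = 1L,
                             estimators = c("naive", "umvcue", "si", "mi",
                                            "shrinkage")) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  K <- design$K
  wanted <- if (identical(estimators, "none")) character(0) else estimators
  est <- lapply(wanted, function(e) matrix(NA_real_, n_reps, K))
  names(est) <- wanted
  selmat <- matrix(FALSE, n_reps, K)
  futility <- rep(NA, n_reps)
  mi_conv <- rep(NA, n_reps)
  n_err <- 0L
  for (i in seq_len(n_reps)) {
    tr <- tryCatch(simulate_trial(design, seed = seeds[i],
                                  estimators = estimators),
                   error = function(e) e)
    if (inherits(tr, "error")) {
      n_err <- n_err + 1L
      next
    }
    futility[i] <- tr$outcome$futility
    selmat[i, tr$outcome$selected] <- TRUE
    if (is.null(tr$fit) || is.null(tr$fit$estimates)) next
    tab <- tr$fit$estimates
    for (e in intersect(wanted, names(tab))) {
      est[[e]][i, tab$arm] <- tab[[e]]
    }
    if (!is.null(tr$fit$mi)) mi_conv[i] <- tr$fit$mi$converged
  }
  structure(list(selected = selmat, futility = futility, estimates = est,
                 mi_converged = mi_conv, n_errors = n_err,
                 design = design, n_reps = n_reps, seed = seed),
            class = "trial_replicates")
}

#' @export
#' @rdname replicate_trials
#' @param object a `trial_replicates` object.
#' @return `summary` returns a data frame with one row per arm: selection
#'   probability and conditional bias / RMSE per estimator.
summary.trial_replicates <- function(object, ...) {
  x <- object
  K <- x$design$K
  ok <- !is.na(x$futility)
  n <- sum(ok)
  rows <- lapply(seq_len(K), function(j) {
    idx <- which(ok & x$selected[, j])
    row <- data.frame(arm = j, selection_prob = length(idx) / n)
    for (e in names(x$estimates)) {
      vals <- x$estimates[[e]][idx, j]
      if (e == "mi") vals <- vals[x$mi_converged[idx] %in% TRUE]
      vals <- vals[!is.na(vals)]
      err <- vals - x$design$theta[j]
      row[[paste0("bias_", e)]] <- if (length(err)) mean(err) else NA_real_
      row[[paste0("rmse_", e)]] <-
        if (length(err)) sqrt(mean(err^2)) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "futility_prob") <- mean(x$futility[ok])
  attr(out, "mi_nonconverged") <- sum(x$mi_converged %in% FALSE)
  attr(out, "n_errors") <- x$n_errors
  out
}

#' @export
print.trial_replicates <- function(x, digits = 4, ...) {
  cat(sprintf("Replicated two-stage trials: n_reps = %d (seed %d)\n",
              x$n_reps, x$seed))
  s <- summary(x)
  cat(sprintf("futility probability: %.*f\n", digits,
              attr(s, "futility_prob")))
  if (attr(s, "n_errors") > 0) {
    cat("replicates with estimation errors:", attr(s, "n_errors"), "\n")
  }
  if ("mi" %in% names(x$estimates)) {
    cat("MI non-convergent replicates:", attr(s, "mi_nonconverged"), "\n")
  }
  s[-1] <- round(s[-1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Required number of events for a two-arm logrank comparison
#'
#' Schoenfeld's formula: with one-to-one allocation,
#' `d = 4 (z_{1-alpha/2} + z_power)^2 / log(hr)^2`, rounded up to the next
#' even integer. For allocation ratio `r` (experimental : control) the factor
#' 4 becomes `(1 + r)^2 / r`.
#'
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @param hr alternative hazard ratio (not 1).
#' @param allocation_ratio experimental-to-control allocation ratio.
#' @return required number of events (even integer).
#' @examples
#' required_events(0.80, 0.05, 0.8)  # 632
#' @export
required_events <- function(power, alpha = 0.05, hr, allocation_ratio = 1) {
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1, hr > 0,
            allocation_ratio > 0)
  if (hr == 1) stop("hr must differ from 1 (required events diverge)",
                    call. = FALSE)
  r <- allocation_ratio
  d <- (1 + r)^2 / r * (qnorm(1 - alpha / 2) + qnorm(power))^2 / log(hr)^2
  2 * ceiling(d / 2)
}
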