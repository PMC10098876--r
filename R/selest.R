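#' Selection-adjusted log hazard ratio estimates for a two-stage trial
#'
#' The main fitting function. Given the stage-wise summary statistics of a
#' seamless phase II/III survival trial (or the per-subject records, from
#' which they are computed) and the interim selection rule, computes, for
#' every selected arm, the naive combined-data estimate and four
#' selection-adjusted estimators:
#'
#' * `umvcue` — the approximate uniformly minimum variance conditional
#'   unbiased estimator ([umvcue_estimate]),
#' * `si` — single-iteration bias-subtracted ([estimate_si]),
#' * `mi` — multiple-iterations bias-subtracted ([estimate_mi]),
#' * `shrinkage` — the two-stage empirical-Bayes shrinkage estimator
#'   ([estimate_shrinkage]).
#'
#' @param x a [stage_summaries] object, or a data frame of per-subject
#'   survival records (see [survival_data]).
#' @param rule a [selection_rule].
#' @param ... passed to methods.
#' @return an object of class `selest`.
#' @examples
#' fit <- selest(worked_example_summaries(),
#'               selection_rule("all_pval_le_a", a = 0.2),
#'               w = 0.5, nu2 = 0)
#' coef(fit, "umvcue")
#' @export
selest <- function(x, rule, ...) UseMethod("selest")

#' @rdname selest
#' @param outcome optional precomputed `selection_outcome`; by default the
#'   rule is applied to the stage-1 estimates in `x`.
#' @param w,nu2,theta1_all,E1,E2 shrinkage controls, see
#'   [estimate_shrinkage].
#' @param mi_tol,mi_max_iter fixed-point controls, see [estimate_mi].
#' @export
selest.stage_summaries <- function(x, rule, outcome = NULL, w = 0.5,
                                   nu2 = "estimate", theta1_all = NULL,
                                   E1 = NULL, E2 = NULL,
                                   mi_tol = 1e-6, mi_max_iter = 100, ...) {
  stopifnot(inherits(rule, "selection_rule"))
  if (is.null(outcome)) outcome <- apply_rule(rule, x$theta1, x$V1)
  out <- structure(list(summaries = x, rule = rule, outcome = outcome,
                        estimates = NULL, mi = NULL, shrinkage = NULL,
                        bounds = NULL),
                   class = "selest")
  if (outcome$futility) return(out)
  sel <- outcome$selected
  if (any(is.na(x$theta2[sel]))) {
    stop("every selected arm needs combined-data estimates in the summaries",
         call. = FALSE)
  }
  bounds <- lapply(sel, function(j) umvcue_bounds(x, outcome, j))
  umv <- vapply(bounds, function(b) umvcue_estimate(x, outcome, b$arm, b),
                numeric(1))
  si <- estimate_si(x, outcome)
  mi <- estimate_mi(x, outcome, tol = mi_tol, max_iter = mi_max_iter)
  sh <- estimate_shrinkage(x, outcome, w = w, nu2 = nu2,
                           theta1_all = theta1_all, E1 = E1, E2 = E2)
  out$estimates <- data.frame(arm = sel,
                              naive = x$theta_full[sel],
                              umvcue = umv,
                              si = as.numeric(si),
                              mi = as.numeric(mi$estimates),
                              shrinkage = as.numeric(sh$estimates),
                              row.names = NULL)
  out$mi <- mi[c("converged", "iterations", "theta_tilde")]
  out$shrinkage <- sh[c("nu2", "w", "stage1")]
  out$bounds <- bounds
  out
}

#' @rdname selest
#' @inheritParams fit_pairwise_cox
#' @export
selest.data.frame <- function(x, rule, interim_time, analysis_time = Inf,
                              stage1_followup = Inf,
                              route = c("cox", "score"), ...) {
  route <- match.arg(route)
  data <- survival_data(x)
  sm0 <- if (route == "cox") {
    fit_stage1_cox(data, interim_time)
  } else {
    K <- n_arms(data)
    th <- V <- numeric(K)
    for (j in seq_len(K)) {
      lr <- logrank_score(data, j, interim_time)
      th[j] <- lr$theta
      V[j] <- lr$V
    }
    list(theta = th, V1 = V)
  }
  outcome <- apply_rule(rule, sm0$theta, sm0$V1)
  if (outcome$futility) {
    summaries <- stage_summaries_from_data(data, integer(0), interim_time,
                                           analysis_time, stage1_followup,
                                           route)
    return(selest(summaries, rule, outcome = outcome, ...))
  }
  summaries <- stage_summaries_from_data(data, outcome$selected,
                                         interim_time, analysis_time,
                                         stage1_followup, route)
  selest(summaries, rule, outcome = outcome, ...)
}

#' @export
print.selest <- function(x, digits = 4, ...) {
  cat("Selection-adjusted log hazard ratio estimates\n")
  print(x$rule)
  if (x$outcome$futility) {
    cat("Futility stop at the interim: no arm selected, no estimates.\n")
    return(invisible(x))
  }
  tab <- x$estimates
  tab[-1] <- round(tab[-1], digits)
  print(tab, row.names = FALSE)
  if (!x$mi$converged) {
    cat("note: MI fixed point did not converge after", x$mi$iterations,
        "iterations; last iterate reported\n")
  }
  invisible(x)
}

#' @export
summary.selest <- function(object, ...) {
  structure(list(fit = object), class = "summary.selest")
}

#' @export
print.summary.selest <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (f$outcome$futility) return(invisible(x))
  cat(sprintf("\nshrinkage: nu2 = %.*g, w = %.*g\n", digits,
              f$shrinkage$nu2, digits, f$shrinkage$w))
  cat(sprintf("MI: converged = %s in %d iteration(s)\n",
              f$mi$converged, f$mi$iterations))
  for (b in f$bounds) {
    cat(sprintf("arm %d stage-2 truncation: BL = %s, BU = %s\n", b$arm,
                format(round(b$BL, digits)), format(round(b$BU, digits))))
  }
  invisible(x)
}

#' @export
#' @rdname selest
#' @param object a `selest` fit.
#' @param estimator which estimator's coefficients to extract.
coef.selest <- function(object,
                        estimator = c("umvcue", "naive", "si", "mi",
                                      "shrinkage"), ...) {
  estimator <- match.arg(estimator)
  if (object$outcome$futility) return(setNames(numeric(0), character(0)))
  setNames(object$estimates[[estimator]],
           paste0("arm", object$estimates$arm))
}
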