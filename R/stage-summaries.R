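#' Stage-wise summary statistics of a two-stage trial
#'
#' The sufficient numerical state for all selection-adjusted estimators:
#' stage-1 log hazard ratio estimates with their covariance, and, per arm
#' with stage-2 data, the combined estimate and information together with the
#' derived independent increment.
#'
#' @param theta1 K-vector of stage-1 log hazard ratio estimates.
#' @param V1 K-vector of stage-1 Fisher informations (`sigma1sq = 1/V1`).
#' @param theta_full,V_full K-vectors of combined-data estimates and
#'   informations; `NA` for arms without stage-2 data.
#' @param Sigma1 optional K x K stage-1 covariance matrix; its diagonal must
#'   equal `1/V1`. Alternatively supply `q`, the off-diagonal covariance(s):
#'   a single value (constant covariance) or a K x K matrix.
#' @param q see `Sigma1`.
#' @param theta1_all optional pooled stage-1 estimate (control vs all
#'   experimental arms combined), used by the shrinkage estimator.
#' @return an object of class `stage_summaries`: a list with fields `K`,
#'   `theta1`, `V1`, `sigma1sq`, `Sigma1`, `theta_full`, `V_full`, `theta2`,
#'   `sigma2sq`, `t` (information fractions `V1/V_full`) and `theta1_all`.
#' @examples
#' stage_summaries(theta1 = c(-0.53, -0.53), V1 = c(8.07, 8.72),
#'                 theta_full = c(-0.65, -0.58), V_full = c(16.6, 16.7),
#'                 q = 0.052)
#' @export
stage_summaries <- function(theta1, V1, theta_full = NULL, V_full = NULL,
                            Sigma1 = NULL, q = NULL, theta1_all = NULL) {
  K <- length(theta1)
  stopifnot(length(V1) == K, all(is.finite(theta1)), all(V1 > 0))
  if (is.null(Sigma1)) {
    Sigma1 <- diag(1 / V1, K)
    if (!is.null(q)) {
      if (is.matrix(q)) {
        Sigma1[row(Sigma1) != col(Sigma1)] <- q[row(q) != col(q)]
      } else {
        Sigma1[row(Sigma1) != col(Sigma1)] <- q
      }
    }
  }
  Sigma1 <- (Sigma1 + t(Sigma1)) / 2
  if (max(abs(diag(Sigma1) - 1 / V1)) > 1e-6 * max(1 / V1)) {
    stop("diag(Sigma1) must equal 1/V1", call. = FALSE)
  }
  if (min(eigen(Sigma1, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(diag(Sigma1))) {
    stop("Sigma1 must be positive semi-definite", call. = FALSE)
  }
  if (is.null(theta_full)) theta_full <- rep(NA_real_, K)
  if (is.null(V_full)) V_full <- rep(NA_real_, K)
  stopifnot(length(theta_full) == K, length(V_full) == K)
  theta2 <- sigma2sq <- tfrac <- rep(NA_real_, K)
  has2 <- !is.na(theta_full) & !is.na(V_full)
  if (any(has2)) {
    inc <- increment_decompose(theta1[has2], V1[has2],
                               theta_full[has2], V_full[has2])
    theta2[has2] <- inc$theta2
    sigma2sq[has2] <- inc$sigma2sq
    tfrac[has2] <- inc$t
  }
  structure(list(K = K, theta1 = as.numeric(theta1), V1 = as.numeric(V1),
                 sigma1sq = 1 / as.numeric(V1), Sigma1 = Sigma1,
                 theta_full = as.numeric(theta_full),
                 V_full = as.numeric(V_full),
                 theta2 = theta2, sigma2sq = sigma2sq, t = tfrac,
                 theta1_all = theta1_all),
            class = "stage_summaries")
}

#' @export
print.stage_summaries <- function(x, digits = 4, ...) {
  cat(sprintf("Stage-wise summaries: %d experimental arm(s) vs control\n",
              x$K))
  tab <- data.frame(theta1 = x$theta1, V1 = x$V1,
                    theta_full = x$theta_full, V_full = x$V_full,
                    theta2 = x$theta2, sigma2sq = x$sigma2sq,
                    row.names = paste0("arm ", seq_len(x$K)))
  print(round(tab, digits))
  if (!is.null(x$theta1_all)) {
    cat(sprintf("pooled stage-1 estimate (all arms vs control): %.*f\n",
                digits, x$theta1_all))
  }
  invisible(x)
}

#' Build stage-wise summaries from per-subject records
#'
#' Runs the full stage-wise estimation pipeline on raw survival records: a
#' stage-1 multi-arm fit at the interim, the shared-control covariance, and,
#' for each arm in `selected`, the combined pairwise fit under the prefixed
#' follow-up rule, with increments decomposed on the score scale.
#'
#' @inheritParams fit_pairwise_cox
#' @param selected integer vector of arms with stage-2 data.
#' @param pooled logical: also compute the pooled stage-1 estimate
#'   (`theta1_all`) needed by the shrinkage estimator.
#' @return a [stage_summaries] object.
#' @export
stage_summaries_from_data <- function(data, selected, interim_time,
                                      analysis_time = Inf,
                                      stage1_followup = Inf,
                                      route = c("cox", "score"),
                                      pooled = TRUE) {
  route <- match.arg(route)
  data <- survival_data(data)
  K <- n_arms(data)
  if (route == "cox") {
    s1 <- fit_stage1_cox(data, interim_time)
    theta1 <- s1$theta
    V1 <- s1$V1
    Sigma1 <- s1$Sigma
  } else {
    theta1 <- V1 <- numeric(K)
    for (j in seq_len(K)) {
      lr <- logrank_score(data, j, interim_time)
      theta1[j] <- lr$theta
      V1[j] <- lr$V
    }
    Sigma1 <- stage1_covariance(data, interim_time)
  }
  theta_full <- V_full <- rep(NA_real_, K)
  for (j in selected) {
    fit <- fit_pairwise_cox(data, j, interim_time, analysis_time,
                            stage1_followup, route)
    theta_full[j] <- fit$theta_full
    V_full[j] <- fit$V_full
  }
  theta1_all <- if (pooled && K >= 1) {
    fit_pooled_stage1(data, interim_time, route)
  }
  stage_summaries(theta1, V1, theta_full, V_full, Sigma1 = Sigma1,
                  theta1_all = theta1_all)
}
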