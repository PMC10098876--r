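#' Multivariate normal rectangle probability
#'
#' `P(lower <= X <= upper)` for `X ~ MVN(mean, sigma)`. Limits may be
#' infinite. Univariate cases use closed forms; dimensions 2-4 use Miwa's
#' deterministic lattice quadrature; higher dimensions (or degenerate
#' covariances) fall back to randomized quasi-Monte-Carlo integration
#' evaluated under a fixed internal RNG state (restored on exit), so
#' repeated calls always return identical values.
#'
#' @param mean m-vector.
#' @param sigma m x m symmetric positive semi-definite covariance matrix.
#' @param lower,upper m-vectors of limits (entries may be `-Inf` / `Inf`).
#' @param abseps absolute accuracy target.
#' @return the probability (scalar).
#' @examples
#' # positive orthant of an equicorrelated (rho = 0.5) bivariate normal: 1/3
#' mvn_rect_prob(c(0, 0), matrix(c(1, .5, .5, 1), 2), c(0, 0), c(Inf, Inf))
#' @export
mvn_rect_prob <- function(mean, sigma, lower, upper, abseps = 1e-8) {
  m <- length(mean)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == m, ncol(sigma) == m,
            length(lower) == m, length(upper) == m, all(lower < upper))
  sigma <- (sigma + t(sigma)) / 2
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(abs(diag(sigma)))) {
    stop("sigma must be positive semi-definite", call. = FALSE)
  }
  if (m == 1L) {
    s <- sqrt(sigma[1, 1])
    return(pnorm(upper, mean, s) - pnorm(lower, mean, s))
  }
  if (m <= 4L) {
    steps <- if (m <= 3L) 512L else 128L
    p <- tryCatch(
      suppressWarnings(   # Miwa notes its +/-1000 stand-in for infinities
        mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                         sigma = sigma,
                         algorithm = mvtnorm::Miwa(steps = steps))),
      error = function(e) NULL)
    if (!is.null(p)) return(max(0, min(1, as.numeric(p))))
  }
  p <- .with_fixed_rng(
    mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                     sigma = sigma,
                     algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                    maxpts = 100000L)))
  max(0, min(1, as.numeric(p)))
}

# evaluate expr under a fixed RNG state, restoring the caller's state
.with_fixed_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(181161L)
  expr
}

#' First moments of a multivariate normal over a rectangle
#'
#' Computes `E[X_k 1{lower <= X <= upper}]` for every coordinate, via the
#' boundary decomposition `E[X 1_R] = mean * P(R) + sigma %*% c`, where
#' `c_k` is the difference of the marginal boundary densities at the lower
#' and upper limits, each multiplied by the (m-1)-dimensional rectangle
#' probability of the conditional distribution on that face. Dividing by
#' [mvn_rect_prob] gives conditional means.
#'
#' @inheritParams mvn_rect_prob
#' @return m-vector of unnormalized first moments.
#' @export
mvn_rect_moments <- function(mean, sigma, lower, upper, abseps = 1e-8) {
  m <- length(mean)
  sigma <- as.matrix(sigma)
  if (m == 1L) {
    s <- sqrt(sigma[1, 1])
    al <- (lower - mean) / s
    au <- (upper - mean) / s
    return(mean * (pnorm(au) - pnorm(al)) - s * (.dnorm0(au) - .dnorm0(al)))
  }
  P <- mvn_rect_prob(mean, sigma, lower, upper, abseps)
  cc <- numeric(m)
  for (k in seq_len(m)) {
    cc[k] <- .face_term(k, lower[k], mean, sigma, lower, upper, abseps) -
             .face_term(k, upper[k], mean, sigma, lower, upper, abseps)
  }
  as.numeric(mean * P + sigma %*% cc)
}

.dnorm0 <- function(x) ifelse(is.finite(x), dnorm(x), 0)

# marginal density at a boundary value times the conditional (m-1)-dim
# rectangle probability on that face; 0 at infinite limits
.face_term <- function(k, x, mean, sigma, lower, upper, abseps) {
  if (!is.finite(x)) return(0)
  sk <- sigma[k, k]
  dens <- dnorm(x, mean[k], sqrt(sk))
  if (dens == 0) return(0)
  mu_c <- mean[-k] + sigma[-k, k] / sk * (x - mean[k])
  sig_c <- sigma[-k, -k, drop = FALSE] -
    tcrossprod(sigma[-k, k, drop = FALSE]) / sk
  dens * mvn_rect_prob(mu_c, sig_c, lower[-k], upper[-k], abseps)
}

#' Selection probability and truncated first moments of stage-1 estimates
#'
#' For a working vector of true log hazard ratios, computes the probability
#' of a selection event and the unnormalized first moments
#' `E[theta1_j 1_S]` of the stage-1 estimators over that event. The
#' computation maps the event to rectangle coordinates
#' (`delta1 = A theta1 ~ MVN(A theta, A Sigma1 A')`), evaluates the
#' rectangle probability and first moments there, and back-transforms the
#' moments by `A^{-1}`.
#'
#' @param theta K-vector of working true effects.
#' @param Sigma1 K x K stage-1 covariance matrix.
#' @param outcome a `selection_outcome` (from [apply_rule]) carrying the
#'   region, or a region list with `A`, `lower`, `upper`.
#' @param prob_floor error if the event probability falls below this floor
#'   (the working mean makes the observed selection numerically impossible).
#' @return list with `prob` and the K-vector `moments`.
#' @export
selection_moments <- function(theta, Sigma1, outcome,
                              prob_floor = .PROB_FLOOR) {
  region <- if (inherits(outcome, "selection_outcome")) outcome$region
            else outcome
  A <- region$A
  mu <- as.numeric(A %*% theta)
  Sd <- A %*% Sigma1 %*% t(A)
  Sd <- (Sd + t(Sd)) / 2
  prob <- mvn_rect_prob(mu, Sd, region$lower, region$upper)
  if (prob < prob_floor) {
    stop(sprintf(paste0("selection probability %.3g below floor %.3g: ",
                        "selection numerically impossible under the ",
                        "supplied mean"), prob, prob_floor), call. = FALSE)
  }
  mom_d <- mvn_rect_moments(mu, Sd, region$lower, region$upper)
  list(prob = prob, moments = as.numeric(solve(A, mom_d)))
}
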