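#' Interim treatment selection rules
#'
#' Constructs one of the six standard interim selection rules. "All"-type
#' rules keep every arm meeting a fixed efficacy threshold; "best"-type rules
#' keep the single most promising arm, optionally subject to a futility
#' threshold. P-value rules act on one-sided pairwise p-values
#' `p_j = Phi(theta1_j * sqrt(V1_j))`, so small p means benefit, and a
#' p-value threshold `a` corresponds to the log hazard ratio bound
#' `Phi^{-1}(a) / sqrt(V1_j)`.
#'
#' @param id one of `"all_loghr_le_b"`, `"all_pval_le_a"`, `"best_loghr"`,
#'   `"best_pval"`, `"best_loghr_le_b"`, `"best_pval_le_a"`.
#' @param a p-value threshold in (0, 1), required by the `_le_a` rules.
#' @param b log hazard ratio threshold, required by the `_le_b` rules.
#' @return an object of class `selection_rule`.
#' @examples
#' selection_rule("all_pval_le_a", a = 0.2)
#' selection_rule("best_loghr_le_b", b = 0)
#' @export
selection_rule <- function(id = c("all_loghr_le_b", "all_pval_le_a",
                                  "best_loghr", "best_pval",
                                  "best_loghr_le_b", "best_pval_le_a"),
                           a = NULL, b = NULL) {
  id <- match.arg(id)
  needs_a <- grepl("_le_a$", id)
  needs_b <- grepl("_le_b$", id)
  if (needs_a && (is.null(a) || !is.finite(a) || a <= 0 || a >= 1)) {
    stop("rule '", id, "' requires a p-value threshold a in (0, 1)",
         call. = FALSE)
  }
  if (needs_b && (is.null(b) || !is.finite(b))) {
    stop("rule '", id, "' requires a finite log hazard ratio threshold b",
         call. = FALSE)
  }
  if (!needs_a) a <- NULL
  if (!needs_b) b <- NULL
  structure(list(id = id,
                 type = if (grepl("^all", id)) "all" else "best",
                 scale = if (grepl("pval", id)) "pval" else "loghr",
                 a = a, b = b),
            class = "selection_rule")
}

#' @export
print.selection_rule <- function(x, ...) {
  lab <- c(all_loghr_le_b = "all arms with log HR <= b",
           all_pval_le_a = "all arms with one-sided p-value <= a",
           best_loghr = "arm with smallest log HR",
           best_pval = "arm with smallest p-value",
           best_loghr_le_b = "arm with smallest log HR, if <= b",
           best_pval_le_a = "arm with smallest p-value, if p <= a")
  cat("Selection rule:", lab[[x$id]], "\n")
  if (!is.null(x$a)) cat("  a =", x$a, "\n")
  if (!is.null(x$b)) cat("  b =", x$b, "\n")
  invisible(x)
}

# per-arm efficacy/futility threshold on the log hazard ratio scale
# (Inf when the rule imposes none)
.rule_threshold <- function(rule, V1) {
  switch(paste(rule$type, rule$scale),
         "all loghr" = rep(rule$b, length(V1)),
         "all pval" = qnorm(rule$a) / sqrt(V1),
         "best loghr" = rep(if (is.null(rule$b)) Inf else rule$b, length(V1)),
         "best pval" = if (is.null(rule$a)) rep(Inf, length(V1))
                       else qnorm(rule$a) / sqrt(V1))
}

#' Apply an interim selection rule to stage-1 estimates
#'
#' Determines the selected set, the futility flag, and, for each selected
#' arm, the conditional bounds `(L_j, W_j)` on its stage-1 estimate given the
#' other arms' estimates. `W_j` is the supremum of stage-1 log hazard ratio
#' values for which arm j would still be selected (the binding constraint:
#' the rule's own threshold and/or the best competitor, rescaled by
#' `sqrt(V1_l / V1_j)` for p-value rules); `L_j = -Inf` for all six rules.
#' Exact ties between arms are broken towards the lowest index.
#'
#' @param rule a [selection_rule].
#' @param theta1 K-vector of stage-1 log hazard ratio estimates.
#' @param V1 K-vector of stage-1 Fisher informations.
#' @return an object of class `selection_outcome`: list with `selected`
#'   (integer vector, possibly empty), `futility`, `W` (K-vector, `NA` for
#'   unselected arms), `L`, `region` (see [selection_region]), plus the rule
#'   and the inputs.
#' @export
apply_rule <- function(rule, theta1, V1) {
  stopifnot(inherits(rule, "selection_rule"),
            length(theta1) == length(V1),
            all(is.finite(theta1)), all(V1 > 0))
  K <- length(theta1)
  u <- .rule_threshold(rule, V1)
  W <- rep(NA_real_, K)
  if (rule$type == "all") {
    selected <- which(theta1 <= u)
    W[selected] <- u[selected]
  } else {
    z <- if (rule$scale == "pval") theta1 * sqrt(V1) else theta1
    jstar <- which.min(z)   # which.min breaks ties at the lowest index
    selected <- if (theta1[jstar] <= u[jstar]) jstar else integer(0)
    if (length(selected)) {
      co <- setdiff(seq_len(K), jstar)
      # competitors on arm jstar's log HR scale
      comp <- if (rule$scale == "pval") {
        theta1[co] * sqrt(V1[co] / V1[jstar])
      } else theta1[co]
      W[jstar] <- min(u[jstar], comp)
    }
  }
  L <- rep(-Inf, K)
  L[-selected] <- NA_real_
  if (!length(selected)) L <- rep(NA_real_, K)
  structure(list(selected = selected, futility = length(selected) == 0L,
                 W = W, L = L,
                 region = selection_region(rule, selected, V1),
                 rule = rule, theta1 = theta1, V1 = V1, K = K),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, digits = 4, ...) {
  if (x$futility) {
    cat("Selection outcome: futility stop (no arm selected)\n")
  } else {
    cat("Selection outcome: selected arm(s)",
        paste(x$selected, collapse = ", "), "\n")
    for (j in x$selected) {
      cat(sprintf("  arm %d: L = %s, W = %.*f\n", j,
                  if (is.finite(x$L[j])) format(x$L[j]) else "-Inf",
                  digits, x$W[j]))
    }
  }
  invisible(x)
}

#' Rectangular representation of a selection event
#'
#' Expresses the event "exactly this set of arms is selected" (or the
#' futility stop) as a rectangle in linearly transformed coordinates:
#' `delta1 = A %*% theta1` with `lower <= delta1 <= upper` componentwise.
#' For threshold ("all"-type) rules `A` is the identity. For best-type rules
#' with selected arm j, row j is the arm's own coordinate (bounded above by
#' the futility threshold, if any) and each competitor row is the contrast
#' `competitor - selected`, rescaled by `sqrt(V1_l / V1_j)` for p-value
#' rules, bounded below by 0.
#'
#' @inheritParams apply_rule
#' @param selected integer vector of selected arms (`integer(0)` for the
#'   futility event).
#' @return list with K x K matrix `A` and K-vectors `lower`, `upper`.
#' @export
selection_region <- function(rule, selected, V1) {
  K <- length(V1)
  u <- .rule_threshold(rule, V1)
  A <- diag(K)
  lower <- rep(-Inf, K)
  upper <- rep(Inf, K)
  if (rule$type == "all") {
    lower[setdiff(seq_len(K), selected)] <- u[setdiff(seq_len(K), selected)]
    upper[selected] <- u[selected]
    return(list(A = A, lower = lower, upper = upper))
  }
  if (!length(selected)) {  # futility for best-type: every arm above its cut
    lower <- u
    return(list(A = A, lower = lower, upper = upper))
  }
  if (length(selected) != 1L) {
    stop("best-type rules select exactly one arm", call. = FALSE)
  }
  j <- selected
  upper[j] <- u[j]
  for (l in setdiff(seq_len(K), j)) {
    A[l, ] <- 0
    A[l, l] <- if (rule$scale == "pval") sqrt(V1[l] / V1[j]) else 1
    A[l, j] <- -1
    lower[l] <- 0
  }
  list(A = A, lower = lower, upper = upper)
}
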