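#' Read / write stage-wise summaries as a flat JSON document
#'
#' The JSON layout mirrors the worked-example table: fields `theta1`, `V1`,
#' `Sigma1` (K x K), `theta_full`, `V_full` (NA/null for arms without
#' stage-2 data) and optionally `theta1_all`. Requires the `jsonlite`
#' package.
#'
#' @param path file path.
#' @return `read_summaries_json` returns a [stage_summaries] object;
#'   `write_summaries_json` returns `path` invisibly.
#' @export
read_summaries_json <- function(path) {
  .need_jsonlite()
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("theta1", "V1")) {
    if (is.null(x[[f]])) stop("summaries JSON lacks field '", f, "'",
                              call. = FALSE)
  }
  Sigma1 <- if (!is.null(x$Sigma1)) matrix(unlist(x$Sigma1),
                                           length(x$theta1))
  stage_summaries(x$theta1, x$V1,
                  theta_full = x$theta_full, V_full = x$V_full,
                  Sigma1 = Sigma1, q = x$q, theta1_all = x$theta1_all)
}

#' @rdname read_summaries_json
#' @param summaries a [stage_summaries] object.
#' @export
write_summaries_json <- function(summaries, path) {
  .need_jsonlite()
  stopifnot(inherits(summaries, "stage_summaries"))
  jsonlite::write_json(
    list(theta1 = summaries$theta1, V1 = summaries$V1,
         Sigma1 = summaries$Sigma1, theta_full = summaries$theta_full,
         V_full = summaries$V_full, theta1_all = summaries$theta1_all),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

.need_jsonlite <- function() {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON input/output",
         call. = FALSE)
  }
}

#' Export a fitted estimate report
#'
#' Writes the per-arm estimate table of a [selest] fit (naive, UMVCUE,
#' single- and multiple-iteration bias-subtracted, shrinkage, plus
#' convergence diagnostics and the truncation bounds used) to CSV or JSON.
#' Values are written at full precision; round for display only.
#'
#' @param fit a [selest] object.
#' @param path output path; format from the extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_estimate_report <- function(fit, path) {
  stopifnot(inherits(fit, "selest"))
  tab <- fit$estimates
  if (!is.null(tab) && !is.null(fit$mi)) {
    tab$mi_converged <- fit$mi$converged
    tab$mi_iterations <- fit$mi$iterations
    tab$nu2 <- fit$shrinkage$nu2
    tab$w <- fit$shrinkage$w
    tab$BL <- vapply(fit$bounds, `[[`, numeric(1), "BL")
    tab$BU <- vapply(fit$bounds, `[[`, numeric(1), "BU")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .need_jsonlite()
    jsonlite::write_json(list(futility = fit$outcome$futility,
                              estimates = tab),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
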