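#' Per-subject survival records for a multi-arm trial
#'
#' Validates a data frame of per-subject records and returns a
#' `survival_data` object. Arms are coded `0` for control and `1..K` for the
#' experimental treatments; times are in days. `recruit_time` is calendar time
#' from trial start, `time` is time on study, and the derived calendar
#' event/censoring time is `recruit_time + time`.
#'
#' @param data data frame with columns `subject_id`, `arm`, `recruit_time`,
#'   `time`, `event` (0/1).
#' @return an object of class `survival_data` (a data frame).
#' @examples
#' d <- survival_data(data.frame(
#'   subject_id = 1:4, arm = c(0, 1, 0, 1),
#'   recruit_time = c(0, 1, 2, 3), time = c(5, 7, 2, 9), event = c(1, 0, 1, 1)
#' ))
#' @export
survival_data <- function(data) {
  need <- c("subject_id", "arm", "recruit_time", "time", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[need]
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop(sprintf("invalid %s in row(s) %s", what,
                   paste(utils::head(which(!ok), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_row(is.finite(data$arm) & data$arm == floor(data$arm) & data$arm >= 0,
          "arm (must be integer >= 0)")
  bad_row(is.finite(data$recruit_time) & data$recruit_time >= 0,
          "recruit_time (must be finite >= 0)")
  bad_row(is.finite(data$time) & data$time > 0, "time (must be > 0)")
  bad_row(data$event %in% c(0, 1), "event (must be 0 or 1)")
  arms <- sort(unique(data$arm))
  if (!identical(as.integer(arms), seq.int(0L, length(arms) - 1L))) {
    stop("arms must form a contiguous set 0..K containing the control (0)",
         call. = FALSE)
  }
  if (anyDuplicated(data$subject_id)) {
    stop("duplicated subject_id: each record must belong to exactly one arm",
         call. = FALSE)
  }
  data$arm <- as.integer(data$arm)
  data$event <- as.integer(data$event)
  class(data) <- c("survival_data", "data.frame")
  data
}

#' Number of experimental arms in a dataset
#' @param data a `survival_data` object.
#' @export
n_arms <- function(data) max(data$arm)

#' Administrative censoring at a calendar analysis time
#'
#' Restricts to subjects recruited strictly before `analysis_time` and censors
#' everyone still at risk at that calendar instant. This is the data freeze
#' applied at an interim or final analysis triggered on the calendar scale.
#'
#' @param data a `survival_data` object.
#' @param analysis_time calendar time (days) of the data freeze.
#' @return a `survival_data` object with follow-up truncated at
#'   `analysis_time`.
#' @export
censor_at <- function(data, analysis_time) {
  data <- data[data$recruit_time < analysis_time, , drop = FALSE]
  cal <- data$recruit_time + data$time
  over <- cal > analysis_time
  data$time[over] <- analysis_time - data$recruit_time[over]
  data$event[over] <- 0L
  class(data) <- c("survival_data", "data.frame")
  data
}

#' Read / write per-subject survival records as CSV
#'
#' The file must have a header row with columns `subject_id`, `arm`,
#' `recruit_time`, `time`, `event`. Malformed rows are reported with their row
#' numbers.
#'
#' @param path file path.
#' @return `read_survival_csv` returns a [survival_data] object;
#'   `write_survival_csv` returns `path` invisibly.
#' @export
read_survival_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  survival_data(raw)
}

#' @rdname read_survival_csv
#' @param data a `survival_data` object (or validatable data frame).
#' @export
write_survival_csv <- function(data, path) {
  data <- survival_data(data)
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
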