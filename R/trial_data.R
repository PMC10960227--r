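# Canonical column order for per-trial records. One row per trial-pair: two
# bisection estimates (seconds) plus the second-order forced choice.
.trial_cols <- c(
  "subject_id", "condition", "total_duration", "trial_index",
  "estimate1", "estimate2", "meta_choice", "feedback_correct"
)

.conditions <- c("V", "A", "AV")

#' Ideal (veridical) metacognitive choice for a trial pair
#'
#' The ideal observer labels as "best" the estimate with the smaller absolute
#' error to the veridical midpoint (`total_duration / 2`). Ties are broken
#' deterministically in favour of interval 1.
#'
#' @param estimate1,estimate2 Numeric vectors of bisection estimates (seconds).
#' @param total_duration Numeric vector of total stimulus durations (seconds).
#' @return Integer vector of 1s and 2s: the interval the ideal observer calls
#'   closest to the veridical midpoint.
#' @export
ideal_choice <- function(estimate1, estimate2, total_duration) {
  mid <- total_duration / 2
  ifelse(abs(estimate2 - mid) < abs(estimate1 - mid), 2L, 1L)
}

#' Assemble and validate a session dataset
#'
#' Builds the canonical per-trial data frame used throughout the package and
#' checks every record-level invariant. `feedback_correct` is always derived
#' from the veridical midpoint (it is never trusted from the input).
#'
#' @param records A data frame containing at least the columns `subject_id`,
#'   `condition` (one of `"V"`, `"A"`, `"AV"`), `total_duration` (seconds),
#'   `trial_index`, `estimate1`, `estimate2` (seconds), `meta_choice` (1 or 2).
#' @param schedule Optional [schedule_spec()] describing the trial schedule;
#'   stored as the `"schedule"` attribute.
#' @return A validated data frame with the canonical column order and a
#'   recomputed `feedback_correct` column.
#' @export
session_data <- function(records, schedule = NULL) {
  records <- as.data.frame(records)
  needed <- setdiff(.trial_cols, "feedback_correct")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  records$subject_id <- as.character(records$subject_id)
  records$condition <- as.character(records$condition)
  records$trial_index <- as.integer(records$trial_index)
  records$meta_choice <- as.integer(records$meta_choice)
  for (col in c("total_duration", "estimate1", "estimate2")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  validate_trials(records)
  records$feedback_correct <- records$meta_choice ==
    ideal_choice(records$estimate1, records$estimate2, records$total_duration)
  records <- records[, .trial_cols]
  if (!is.null(schedule)) attr(records, "schedule") <- schedule
  records
}

#' Validate per-trial records
#'
#' Checks the record-level invariants: conditions are known labels, durations
#' positive, each bisection estimate lies in `[0, total_duration]` (a response
#' cannot precede stimulus onset or follow its offset), the metacognitive
#' choice is 1 or 2, and trial indices are unique positive integers within
#' each subject-condition-duration cell. Errors name the first offending row.
#'
#' @param records Data frame of trial records.
#' @return Invisibly, `records`.
#' @export
validate_trials <- function(records) {
  fail <- function(rows, what) {
    stop(sprintf("invalid trial record(s) at row(s) %s: %s",
                 paste(utils::head(which(rows), 5), collapse = ", "), what),
         call. = FALSE)
  }
  if (nrow(records) == 0) return(invisible(records))
  bad <- !(records$condition %in% .conditions)
  if (any(bad)) fail(bad, "condition must be one of V, A, AV")
  bad <- !is.finite(records$total_duration) | records$total_duration <= 0
  if (any(bad)) fail(bad, "total_duration must be a positive number")
  for (col in c("estimate1", "estimate2")) {
    x <- records[[col]]
    bad <- !is.finite(x) | x < 0 | x > records$total_duration
    if (any(bad)) fail(bad, sprintf("%s must lie in [0, total_duration]", col))
  }
  bad <- !(records$meta_choice %in% c(1L, 2L))
  if (any(bad)) fail(bad, "meta_choice must be 1 or 2")
  bad <- is.na(records$trial_index) | records$trial_index < 1
  if (any(bad)) fail(bad, "trial_index must be a positive integer")
  key <- interaction(records$subject_id, records$condition,
                     records$total_duration, drop = TRUE)
  dup <- ave(records$trial_index, key, FUN = function(i) duplicated(i)) > 0
  if (any(dup)) fail(dup, "trial_index duplicated within subject-condition")
  invisible(records)
}

#' Read per-trial records from delimited text
#'
#' Reads a session table written by [write_trials()] (or any delimited file
#' with the canonical header), validates every record, and recomputes
#' `feedback_correct` from the veridical midpoint. A JSON sidecar
#' (`<path>.schedule.json`), if present, is attached as the `"schedule"`
#' attribute.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default comma).
#' @param units Unit of the duration/estimate columns in the file; `"ms"`
#'   values are converted to seconds on read.
#' @return A validated session data frame (seconds).
#' @export
read_trials <- function(path, delim = ",", units = c("s", "ms")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (units == "ms") {
    for (col in c("total_duration", "estimate1", "estimate2")) {
      if (col %in% names(df)) df[[col]] <- df[[col]] / 1000
    }
  }
  sidecar <- paste0(path, ".schedule.json")
  schedule <- if (file.exists(sidecar)) {
    do.call(schedule_spec, jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  session_data(df, schedule = schedule)
}

#' Write per-trial records to delimited text
#'
#' Writes the canonical column order with full-precision numbers (17
#' significant digits, so that `read_trials(write_trials(x)) == x` bit-exactly)
#' and, when a schedule is attached, a JSON sidecar at
#' `<path>.schedule.json`.
#'
#' @param data Validated session data frame (see [session_data()]).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return Invisibly, `path`.
#' @export
write_trials <- function(data, path, delim = ",") {
  data <- session_data(data, schedule = attr(data, "schedule"))
  out <- data
  for (col in c("total_duration", "estimate1", "estimate2")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  out$feedback_correct <- ifelse(out$feedback_correct, "TRUE", "FALSE")
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write trials to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  schedule <- attr(data, "schedule")
  if (!is.null(schedule)) {
    jsonlite::write_json(unclass(schedule), paste0(path, ".schedule.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
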