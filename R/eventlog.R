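#' @include AllClasses.R
NULL

EVENT_LOG_COLS <- c("timestamp", "channel", "event_class", "f0_hz",
                    "duration_s", "amplitude", "score")

#' Create an empty event log
#'
#' An event log is a plain data.frame with one row per detected pulse:
#' absolute timestamp (UTC seconds), channel label, class label from
#' \code{\link{EVENT_CLASSES}}, fundamental frequency (Hz, NA when not
#' measured), duration (s), peak amplitude (a.u.) and discriminant score.
#'
#' @return zero-row data.frame with the event-log columns.
#' @export
emptyEventLog <- function() {
  data.frame(timestamp = numeric(0), channel = character(0),
             event_class = character(0), f0_hz = numeric(0),
             duration_s = numeric(0), amplitude = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Validate an event log
#'
#' Checks the column contract, the class vocabulary, and that timestamps are
#' non-decreasing within each channel.
#'
#' @param log event-log data.frame.
#' @return the log, invisibly; errors describe the first violation.
#' @export
validateEventLog <- function(log) {
  miss <- setdiff(EVENT_LOG_COLS, names(log))
  if (length(miss))
    stop("event log missing column(s): ", paste(miss, collapse = ", "))
  bad <- !log$event_class %in% EVENT_CLASSES
  if (any(bad))
    stop("unknown event_class at row ", which(bad)[1], ": ",
         log$event_class[which(bad)[1]])
  for (ch in unique(log$channel)) {
    ts <- log$timestamp[log$channel == ch]
    if (is.unsorted(ts))
      stop("timestamps not non-decreasing within channel ", ch)
  }
  invisible(log)
}

#' Write an event log as CSV
#'
#' Rows are sorted by timestamp before writing; timestamps are written with
#' microsecond precision so the CSV round trip is lossless to 1e-6 s.
#'
#' @param log event-log data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEventLog <- function(log, path) {
  log <- log[order(log$timestamp), , drop = FALSE]
  validateEventLog(log)
  out <- log[, EVENT_LOG_COLS, drop = FALSE]
  out$timestamp <- sprintf("%.6f", out$timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event log CSV
#'
#' @param path CSV path with header
#'   \code{timestamp,channel,event_class,f0_hz,duration_s,amplitude,score}.
#' @return validated event-log data.frame.
#' @export
readEventLog <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != length(EVENT_LOG_COLS))
  if (length(bad))
    stop("malformed event log ", path, " at line ", bad[1], ": expected ",
         length(EVENT_LOG_COLS), " fields, found ", nf[bad[1]],
         call. = FALSE)
  log <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(timestamp = "numeric",
                                   channel = "character",
                                   event_class = "character",
                                   f0_hz = "numeric", duration_s = "numeric",
                                   amplitude = "numeric", score = "numeric")),
    error = function(e) {
      # locate the offending line for the diagnostic
      lines <- readLines(path)
      nf <- lengths(regmatches(lines, gregexpr(",", lines)))
      bad <- which(nf != nf[1])
      stop("malformed event log ", path,
           if (length(bad)) paste0(" at line ", bad[1]) else "",
           ": ", conditionMessage(e), call. = FALSE)
    })
  validateEventLog(log)
  log
}
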