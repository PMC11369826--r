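.EVENT_TYPES <- c("turn_left", "turn_right", "turn", "doorway", "stop",
                  "start", "freeze", "stand")
.TRIGGERS <- c("turn", "doorway", "start", "destination", "walking", "none")
.SOURCES <- c("rater_A", "rater_B", "consensus", "kinematics", "protocol")

#' Build a validated event table
#'
#' Events are typed half-open intervals `[onset, onset + duration)` in
#' seconds from run start. `freeze` events must carry a trigger class
#' (`turn`, `doorway`, `start`, `destination` or `walking`); other events
#' carry `none` unless stated. Rows are returned sorted by onset.
#'
#' @param onset Numeric vector, seconds (>= 0).
#' @param duration Numeric vector, seconds (>= 0).
#' @param type Event type: one of `r paste(.EVENT_TYPES, collapse=", ")`.
#' @param trigger Trigger class per row.
#' @param source Annotation source per row (`rater_A`, `rater_B`,
#'   `consensus`, `kinematics`, `protocol`).
#' @param run Optional run identifier per row.
#' @return A `data.frame` with class `"event_table"` prepended, columns
#'   `onset`, `duration`, `type`, `trigger`, `source`, `run`.
#' @examples
#' eventTable(onset = c(30, 10), duration = c(2, 3),
#'            type = c("freeze", "stop"), trigger = c("turn", "none"))
#' @export
eventTable <- function(onset = numeric(), duration = numeric(),
                       type = character(), trigger = "none",
                       source = "protocol", run = "run-01") {
  n <- length(onset)
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   type = rep_len(as.character(type), n),
                   trigger = rep_len(as.character(trigger), max(n, 0)),
                   source = rep_len(as.character(source), max(n, 0)),
                   run = rep_len(as.character(run), max(n, 0)),
                   stringsAsFactors = FALSE)
  if (n == 0L) df <- df[0L, ]
  df <- df[order(df$run, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", class(df))
  validateEvents(df)
  df
}

#' Validate an event table
#'
#' Checks the event-table invariants: non-negative onsets and durations,
#' known type/trigger/source labels, rows sorted by onset within run,
#' freeze rows carrying a trigger, and no overlapping duplicate consensus
#' freeze rows.
#'
#' @param events An event table (`data.frame` as built by [eventTable()]).
#' @return `events`, invisibly; stops on violation.
#' @export
validateEvents <- function(events) {
  need <- c("onset", "duration", "type", "trigger", "source")
  if (!all(need %in% names(events)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$onset < 0)) stop("event onsets must be >= 0")
  if (any(events$duration < 0)) stop("event durations must be >= 0")
  if (!all(events$type %in% .EVENT_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(events$type, .EVENT_TYPES), collapse = ", "))
  if (!all(events$trigger %in% .TRIGGERS))
    stop("unknown trigger(s): ",
         paste(setdiff(events$trigger, .TRIGGERS), collapse = ", "))
  if (!all(events$source %in% .SOURCES))
    stop("unknown source(s): ",
         paste(setdiff(events$source, .SOURCES), collapse = ", "))
  run <- if ("run" %in% names(events)) events$run else "run-01"
  for (r in unique(run)) {
    o <- events$onset[run == r]
    if (is.unsorted(o)) stop("events must be sorted by onset within run")
  }
  fz <- events[events$type == "freeze", , drop = FALSE]
  if (any(fz$trigger == "none"))
    stop("freeze events must carry a trigger class")
  cf <- fz[fz$source == "consensus", , drop = FALSE]
  if (nrow(cf) > 1L) {
    runf <- if ("run" %in% names(cf)) cf$run else "run-01"
    for (r in unique(runf)) {
      x <- cf[runf == r, , drop = FALSE]
      x <- x[order(x$onset), , drop = FALSE]
      if (nrow(x) > 1L &&
          any(x$onset[-1L] < (x$onset + x$duration)[-nrow(x)]))
        stop("overlapping consensus freeze rows in run ", r)
    }
  }
  invisible(events)
}

#' Read / write BIDS-style events tables
#'
#' Events are stored as tab-separated text with columns `onset`, `duration`,
#' `trial_type`, `trigger`, `source` and `run`. `loadEvents()` validates and
#' returns rows sorted by onset; `writeEvents(loadEvents(p))` round-trips
#' all fields.
#'
#' @param path File path (`.tsv`).
#' @param events An event table.
#' @return `loadEvents()`: an event table; `writeEvents()`: `path`,
#'   invisibly.
#' @export
writeEvents <- function(path, events) {
  validateEvents(events)
  out <- data.frame(onset = format(events$onset, digits = 17,
                                   scientific = FALSE, trim = TRUE),
                    duration = format(events$duration, digits = 17,
                                      scientific = FALSE, trim = TRUE),
                    trial_type = events$type, trigger = events$trigger,
                    source = events$source,
                    run = if ("run" %in% names(events)) events$run
                          else "run-01")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
loadEvents <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(onset = "numeric",
                                         duration = "numeric",
                                         trial_type = "character",
                                         trigger = "character",
                                         source = "character",
                                         run = "character"))
  eventTable(onset = df$onset, duration = df$duration, type = df$trial_type,
             trigger = df$trigger, source = df$source, run = df$run)
}

## interval helpers shared by gait-event logic -------------------------------

# union length of a set of [onset, end) intervals
.intervalUnionLength <- function(onset, duration) {
  if (length(onset) == 0L) return(0)
  o <- order(onset)
  on <- onset[o]; en <- (onset + duration)[o]
  tot <- 0; cur_s <- on[1L]; cur_e <- en[1L]
  for (i in seq_along(on)[-1L]) {
    if (on[i] <= cur_e) cur_e <- max(cur_e, en[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- on[i]; cur_e <- en[i] }
  }
  tot + (cur_e - cur_s)
}
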