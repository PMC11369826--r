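#' Event-locked epoching with baseline correction
#'
#' For each event and each unmasked channel row, the epoch value is the
#' mean signal over `window` seconds from the event onset minus the mean
#' over the `baseline` window, both half-open `[a, b)` relative to onset.
#' The default windows follow the study design: early response 0-3 s
#' (all events), late response 7-10 s (stops and starts, capturing
#' standing/walking), baseline -10 to -5 s (stable walking or standing
#' before any instruction). Events without full window-plus-baseline
#' margin inside the recording are dropped (their count is reported in
#' the `dropped` attribute).
#'
#' @param z A [FnirsRecording-class] (typically z-units; any unit works).
#' @param events Event table for the recording's run.
#' @param window Length-2 numeric, response window `[a, b)` seconds from
#'   onset.
#' @param baseline Length-2 numeric, baseline window (default `c(-10, -5)`).
#' @param window_label Label stored in the `window` column (`"early"`,
#'   `"late"`).
#' @return Long-format `data.frame`: `run`, `event_id`, `condition`,
#'   `onset`, `trigger`, `row_id`, `channel`, `chromophore`, `window`,
#'   `value`.
#' @export
epochEvents <- function(z, events, window = c(0, 3), baseline = c(-10, -5),
                        window_label = if (window[1] >= 7) "late"
                                       else "early") {
  fs <- samplingRate(z)
  n <- nSamples(z)
  rows <- which(!z@mask)
  out <- list(); dropped <- 0L
  meanWin <- function(r, a, b) {
    i0 <- 1L + floor((a - z@time0) * fs)
    i1 <- ceiling((b - z@time0) * fs)       # [a, b): last index i1
    mean(z@data[r, i0:i1])
  }
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    a0 <- on + baseline[1]; b1 <- on + window[2]
    if ((a0 - z@time0) * fs < 0 || (b1 - z@time0) * fs > n) {
      dropped <- dropped + 1L
      next
    }
    cond <- .conditionOf(events[i, , drop = FALSE])
    for (r in rows) {
      out[[length(out) + 1L]] <- data.frame(
        run = if ("run" %in% names(events)) events$run[i] else z@runId,
        event_id = sprintf("%s_%03d", events$type[i], i),
        condition = cond, onset = on, trigger = events$trigger[i],
        type = events$type[i],
        row_id = rownames(z@data)[r], channel = z@channel[r],
        chromophore = z@chromophore[r], window = window_label,
        value = meanWin(r, on + window[1], on + window[2]) -
          meanWin(r, on + baseline[1], on + baseline[2]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(run = character(), event_id = character(),
               condition = character(), onset = numeric(),
               trigger = character(), type = character(),
               row_id = character(), channel = character(),
               chromophore = character(), window = character(),
               value = numeric(), stringsAsFactors = FALSE)
  attr(res, "dropped") <- dropped
  res
}

#' Average channel-level epoch values into ROIs
#'
#' Unweighted mean of the unmasked channels belonging to each ROI, per
#' event and window; ROIs with no remaining channels yield no row.
#'
#' @param table Channel-level epoch table from [epochEvents()].
#' @param montage The [FnirsMontage-class] supplying the channel-to-ROI
#'   map.
#' @return ROI-level epoch table with `roi` replacing
#'   `row_id`/`channel`.
#' @export
roiAverage <- function(table, montage) {
  if (!nrow(table)) {
    out <- table[, setdiff(names(table), c("row_id", "channel"))]
    out$roi <- character(0)
    return(out)
  }
  rmap <- roiOf(montage, unique(table$channel))
  table$roi <- rmap[table$channel]
  table <- table[!is.na(table$roi) & table$roi != "none", , drop = FALSE]
  agg <- stats::aggregate(
    value ~ run + event_id + condition + onset + trigger + type +
      chromophore + window + roi,
    data = table, FUN = mean)
  agg[order(agg$run, agg$onset, agg$roi), , drop = FALSE]
}

#' Assemble a freeze / stop / successful condition table
#'
#' Restructures an ROI-level epoch table for the condition model: freezes
#' of the given trigger become `freeze`, voluntary stops become `stop`,
#' and successful events of the trigger's own type become `successful`;
#' everything else is dropped. Early-window rows only.
#'
#' @param epochs ROI-level epoch table (with `participant` attached).
#' @param trigger `"turn"` or `"doorway"` -- the freeze trigger analysed.
#' @return Data frame with `value`, `participant`, `condition`, `roi`.
#' @export
buildConditionTable <- function(epochs, trigger = "turn") {
  e <- epochs[epochs$window == "early", , drop = FALSE]
  cond <- ifelse(e$condition == "freeze" & e$trigger == trigger, "freeze",
          ifelse(e$condition == "stop", "stop",
          ifelse(e$condition == trigger, "successful", NA)))
  keep <- !is.na(cond)
  out <- e[keep, , drop = FALSE]
  out$condition <- cond[keep]
  out
}

#' Pool left and right turns
#'
#' Relabels `turn_left`/`turn_right` rows as `turn`, keeping the original
#' direction in a `direction` column for audit. Idempotent.
#'
#' @param table An epoch table (or event-like data.frame with a `type`
#'   column).
#' @return The table with pooled turn labels.
#' @export
poolTurns <- function(table) {
  if (!nrow(table)) return(table)
  if (!"direction" %in% names(table))
    table$direction <- ifelse(table$type == "turn_left", "left",
                              ifelse(table$type == "turn_right", "right",
                                     NA_character_))
  turn <- table$type %in% c("turn_left", "turn_right")
  table$type[turn] <- "turn"
  if ("condition" %in% names(table))
    table$condition[table$condition %in% c("turn_left", "turn_right")] <-
      "turn"
  table
}
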