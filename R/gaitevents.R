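#' Detect gait events from kinematics
#'
#' Deterministic kinematic definitions:
#' \itemize{
#'   \item stop onset: walking velocity falls below `v_stop` and stays
#'     below it for at least `min_halt_s` seconds;
#'   \item start onset: velocity rises back above `v_stop` after a stop;
#'   \item turn onset: yaw angular speed, reconstructed from the vertical
#'     head angular acceleration by leaky integration (2 s time constant,
#'     bounding drift), exceeds `omega_turn` for at least 0.5 s;
#'   \item doorway onset: planar position crosses the door plane
#'     (`door_x`), requiring approach from beyond `door_margin_m` on one
#'     side and departure beyond it on the other within `door_window_s`.
#' }
#'
#' @param kin A [GaitKinematics-class].
#' @param geometry List with `door_x` (door-plane coordinate, m); if
#'   `NULL`, doorway detection is skipped with a warning.
#' @param v_stop Stop threshold, m/s (0.1).
#' @param min_halt_s Minimum halt duration, s (2).
#' @param omega_turn Turn threshold, deg/s (30).
#' @param door_margin_m,door_window_s Doorway crossing requirements.
#' @return An event table (`source = "kinematics"`).
#' @export
detectGaitEvents <- function(kin, geometry = NULL, v_stop = 0.1,
                             min_halt_s = 2, omega_turn = 30,
                             door_margin_m = 0.3, door_window_s = 5) {
  fs <- samplingRate(kin)
  v <- kin@data[, "velocity"]
  n <- length(v)
  tt <- kin@time0 + (seq_len(n) - 1) / fs

  onset <- numeric(); duration <- numeric(); type <- character()
  ## stops & starts from halts of >= min_halt_s below v_stop
  below <- v < v_stop
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= min_halt_s * fs)) {
    onset <- c(onset, tt[starts[i]])
    duration <- c(duration, (ends[i] - starts[i] + 1L) / fs)
    type <- c(type, "stop")
    if (ends[i] < n) {
      onset <- c(onset, tt[ends[i] + 1L])
      duration <- c(duration, 0)
      type <- c(type, "start")
    }
  }
  ## turns: yaw rate by leaky integration of the vertical angular
  ## acceleration (the leak bounds sensor-noise drift)
  lam <- exp(-1 / (2 * fs))
  rate <- stats::filter(kin@data[, "angacc_z"] / fs, lam,
                        method = "recursive")
  rate <- abs(as.numeric(rate)) * 180 / pi
  rate <- .movAvg(rate, round(0.2 * fs))
  fast <- rate > omega_turn
  r <- rle(fast)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= 0.5 * fs)) {
    onset <- c(onset, tt[starts[i]])
    duration <- c(duration, (ends[i] - starts[i] + 1L) / fs)
    type <- c(type, "turn")
  }
  ## doorway crossings
  if (is.null(geometry) || is.null(geometry$door_x)) {
    warning("no door geometry; doorway events skipped")
  } else {
    s <- kin@data[, "pos_x"] - geometry$door_x
    w <- round(door_window_s * fs)
    cross <- which(s[-1] * s[-n] < 0 | (s[-n] != 0 & s[-1] == 0))
    for (ci in cross) {
      lo <- max(1L, ci - w); hi <- min(n, ci + w)
      if (any(s[lo:ci] < -door_margin_m) && any(s[ci:hi] > door_margin_m) ||
          any(s[lo:ci] > door_margin_m) && any(s[ci:hi] < -door_margin_m)) {
        onset <- c(onset, tt[ci + 1L]); duration <- c(duration, 0)
        type <- c(type, "doorway")
      }
    }
  }
  ## merge doorway duplicates closer than 1 s (single pass = one event)
  ev <- data.frame(onset = onset, duration = duration, type = type,
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  last <- list()
  for (i in seq_len(nrow(ev))) {
    ty <- ev$type[i]
    if (!is.null(last[[ty]]) && ev$onset[i] - last[[ty]] < 1) keep[i] <- FALSE
    else last[[ty]] <- ev$onset[i]
  }
  ev <- ev[keep, , drop = FALSE]
  eventTable(onset = ev$onset, duration = ev$duration, type = ev$type,
             trigger = "none", source = "kinematics")
}

#' Merge two raters' freeze annotations
#'
#' Freeze intervals from the two raters whose intervals come within
#' `tolerance_s` of each other are combined into consensus events by
#' interval union (the `include` correction); annotations with no
#' counterpart within tolerance are surfaced as disputed for manual
#' resolution. The operation is symmetric in its arguments.
#'
#' @param a,b Freeze-only event tables from the two raters.
#' @param tolerance_s Matching tolerance in seconds (2).
#' @return List: `consensus` (event table, `source = "consensus"`) and
#'   `disputed` (event table of unmatched annotations).
#' @export
mergeAnnotations <- function(a, b, tolerance_s = 2) {
  stopifnot(all(a$type == "freeze"), all(b$type == "freeze"))
  runs <- union(unique(a$run), unique(b$run))
  cons <- list(); disp <- list()
  for (r in runs) {
    ar <- a[a$run == r, , drop = FALSE]
    br <- b[b$run == r, , drop = FALSE]
    pool <- rbind(cbind(ar, who = "A"), cbind(br, who = "B"))
    if (!nrow(pool)) next
    pool <- pool[order(pool$onset), , drop = FALSE]
    # connected components under gap <= tolerance between intervals
    comp <- integer(nrow(pool)); cid <- 0L; lastEnd <- -Inf
    for (i in seq_len(nrow(pool))) {
      if (pool$onset[i] - lastEnd > tolerance_s) cid <- cid + 1L
      comp[i] <- cid
      lastEnd <- max(lastEnd, pool$onset[i] + pool$duration[i])
    }
    for (g in unique(comp)) {
      grp <- pool[comp == g, , drop = FALSE]
      on <- min(grp$onset); en <- max(grp$onset + grp$duration)
      trig <- grp$trigger[1]
      if (all(c("A", "B") %in% grp$who)) {
        cons[[length(cons) + 1L]] <- data.frame(
          onset = on, duration = en - on, trigger = trig, run = r,
          stringsAsFactors = FALSE)
      } else {
        disp[[length(disp) + 1L]] <- data.frame(
          onset = on, duration = en - on, trigger = trig, run = r,
          who = grp$who[1], stringsAsFactors = FALSE)
      }
    }
  }
  consensus <- if (length(cons)) {
    cc <- do.call(rbind, cons)
    eventTable(onset = cc$onset, duration = cc$duration, type = "freeze",
               trigger = cc$trigger, source = "consensus", run = cc$run)
  } else eventTable()
  disputed <- if (length(disp)) {
    dd <- do.call(rbind, disp)
    out <- eventTable(onset = dd$onset, duration = dd$duration,
                      type = "freeze", trigger = dd$trigger,
                      source = "consensus", run = dd$run)
    out$source <- ifelse(dd$who[order(dd$run, dd$onset)] == "A",
                         "rater_A", "rater_B")
    out
  } else eventTable()
  list(consensus = consensus, disputed = disputed)
}

#' Inter-rater agreement on a sampled timeline
#'
#' Samples the task timeline at `sample_rate` Hz; each sample is scored
#' frozen/not-frozen under each rater, giving counts `n11` (both frozen),
#' `n10`, `n01` and `n00`. Positive agreement
#' `= 2 n11 / (2 n11 + n10 + n01)`, negative agreement
#' `= 2 n00 / (2 n00 + n10 + n01)`, prevalence index
#' `= (n11 - n00) / N`. With no freezes from either rater the positive
#' agreement is undefined and reported as `NaN`.
#'
#' @param a,b Freeze-only event tables.
#' @param total_duration_s Task duration covered by the timeline.
#' @param sample_rate Sampling rate of the agreement timeline, Hz (1).
#' @return List with `positive_agreement`, `negative_agreement`,
#'   `prevalence_index`, `n_samples`, `sample_rate`, and the 2x2 counts.
#' @export
agreementMetrics <- function(a, b, total_duration_s, sample_rate = 1) {
  n <- floor(total_duration_s * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  inA <- .coveredBy(tt, a)
  inB <- .coveredBy(tt, b)
  n11 <- sum(inA & inB); n00 <- sum(!inA & !inB)
  n10 <- sum(inA & !inB); n01 <- sum(!inA & inB)
  pos <- if (2 * n11 + n10 + n01 == 0) NaN else
    2 * n11 / (2 * n11 + n10 + n01)
  neg <- if (2 * n00 + n10 + n01 == 0) NaN else
    2 * n00 / (2 * n00 + n10 + n01)
  list(positive_agreement = pos, negative_agreement = neg,
       prevalence_index = (n11 - n00) / n, n_samples = n,
       sample_rate = sample_rate,
       counts = c(n11 = n11, n10 = n10, n01 = n01, n00 = n00))
}

# which sample times fall inside any [onset, onset+duration) interval
.coveredBy <- function(tt, events) {
  out <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(events)))
    out <- out | (tt >= events$onset[i] &
                    tt < events$onset[i] + events$duration[i])
  out
}

#' Select analysis-ready events
#'
#' Applies the study's exclusion rules per run: a freeze is retained only
#' when not preceded by another freezing event within `exclusion_s`
#' seconds (gap measured from the previous freeze's end to this onset);
#' a detected gait event is retained as "successful" only when no freeze
#' intersects `[onset - exclusion_s, onset + exclusion_s]`. Freezes are
#' (re-)labelled with the trigger of the nearest detected event within
#' `trigger_window_s`, else `"walking"`.
#'
#' @param freezes Consensus freeze event table.
#' @param detected Detected/protocol gait events (turn/doorway/stop/start).
#' @param exclusion_s The 10 s rule window.
#' @param trigger_window_s Trigger-attribution window (5 s).
#' @return Event table of retained freezes (type `freeze`) and successful
#'   events (original types), sorted by onset; idempotent.
#' @export
selectEvents <- function(freezes, detected, exclusion_s = 10,
                         trigger_window_s = 5) {
  out <- list()
  runs <- union(unique(freezes$run), unique(detected$run))
  for (r in runs) {
    fz <- freezes[freezes$run == r, , drop = FALSE]
    dv <- detected[detected$run == r & detected$type != "freeze", ,
                   drop = FALSE]
    fz <- fz[order(fz$onset), , drop = FALSE]
    keepF <- rep(TRUE, nrow(fz))
    for (i in seq_len(nrow(fz))) {
      prevEnds <- fz$onset[-i] + fz$duration[-i]
      prevOn <- fz$onset[-i]
      near <- prevOn < fz$onset[i] &
        prevEnds > fz$onset[i] - exclusion_s
      if (any(near)) keepF[i] <- FALSE
    }
    fz <- fz[keepF, , drop = FALSE]
    # trigger attribution by nearest detected event
    if (nrow(fz) && nrow(dv)) {
      for (i in seq_len(nrow(fz))) {
        dist <- abs(dv$onset - fz$onset[i])
        j <- which.min(dist)
        fz$trigger[i] <- if (dist[j] <= trigger_window_s) {
          switch(dv$type[j],
                 turn_left = "turn", turn_right = "turn", turn = "turn",
                 doorway = "doorway", start = "start",
                 stop = "destination", "walking")
        } else "walking"
      }
    }
    # successful events: no freeze within +/- exclusion window
    allFz <- freezes[freezes$run == r, , drop = FALSE]
    keepD <- rep(TRUE, nrow(dv))
    for (i in seq_len(nrow(dv))) {
      hit <- allFz$onset < dv$onset[i] + exclusion_s &
        allFz$onset + allFz$duration > dv$onset[i] - exclusion_s
      if (any(hit)) keepD[i] <- FALSE
    }
    dv <- dv[keepD, , drop = FALSE]
    if (nrow(fz)) out[[length(out) + 1L]] <- fz
    if (nrow(dv)) out[[length(out) + 1L]] <- dv
  }
  if (!length(out)) return(eventTable())
  all <- do.call(rbind, out)
  eventTable(onset = all$onset, duration = all$duration, type = all$type,
             trigger = all$trigger, source = all$source, run = all$run)
}

#' Percentage of task time spent frozen
#'
#' Union length of the (optionally trigger-filtered) freeze intervals,
#' as a percentage of the total gait-task duration.
#'
#' @param freezes Consensus freeze table.
#' @param task_duration_s Total task duration, seconds.
#' @param trigger Optional trigger filter (e.g. `"doorway"`).
#' @return Percentage in `[0, 100]`.
#' @export
percentTimeFrozen <- function(freezes, task_duration_s, trigger = NULL) {
  fz <- freezes[freezes$type == "freeze", , drop = FALSE]
  if (!is.null(trigger)) fz <- fz[fz$trigger %in% trigger, , drop = FALSE]
  if (!nrow(fz)) return(0)
  tot <- 0
  for (r in unique(fz$run)) {
    fr <- fz[fz$run == r, , drop = FALSE]
    tot <- tot + .intervalUnionLength(fr$onset, fr$duration)
  }
  100 * tot / task_duration_s
}

#' Behavioural statistics around gait events
#'
#' Per participant, mean walking speed and window-averaged accelerations
#' (last 3 s before stops, 2 s before turns and doorway passages, first
#' 3 s after starts), then Welch two-sample group comparisons and
#' one-sample tests against zero.
#'
#' @param kins Named list of [GaitKinematics-class] (or per-participant
#'   lists of them, one per run).
#' @param eventsByPart Named list of event tables aligned with `kins`.
#' @param groups Named character vector (`"PD"`/`"HC"`) per participant.
#' @return List: `per_participant` data.frame of window summaries and
#'   `tests` data.frame of t statistics (two-sample per measure, and
#'   one-sample per group for the doorway deceleration).
#' @export
behaviourStats <- function(kins, eventsByPart, groups) {
  summ <- lapply(names(kins), function(pid) {
    kl <- kins[[pid]]
    if (is(kl, "GaitKinematics")) kl <- list(kl)
    ev <- eventsByPart[[pid]]
    speeds <- c(); dstop <- c(); dturn <- c(); ddoor <- c(); astart <- c()
    for (j in seq_along(kl)) {
      kin <- kl[[j]]
      evr <- if ("run" %in% names(ev) && length(kl) > 1)
        ev[ev$run == sprintf("run-%02d", j), , drop = FALSE] else ev
      fs <- samplingRate(kin)
      v <- kin@data[, "velocity"]
      speeds <- c(speeds, mean(v[v > 0.3]))
      win <- function(t0, t1) {
        i0 <- max(1L, 1L + round((t0 - kin@time0) * fs))
        i1 <- min(length(v), round((t1 - kin@time0) * fs))
        if (i1 <= i0) return(NA_real_)
        (v[i1] - v[i0]) / ((i1 - i0) / fs)
      }
      for (o in evr$onset[evr$type == "stop"])
        dstop <- c(dstop, win(o - 3, o))
      for (o in evr$onset[evr$type %in% c("turn_left", "turn_right",
                                          "turn")])
        dturn <- c(dturn, win(o - 2, o))
      for (o in evr$onset[evr$type == "doorway"])
        ddoor <- c(ddoor, win(o - 2, o))
      for (o in evr$onset[evr$type == "start"])
        astart <- c(astart, win(o, o + 3))
    }
    avg <- function(v) if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    data.frame(participant = pid, group = groups[[pid]],
               speed = avg(speeds), decel_stop = avg(dstop),
               decel_turn = avg(dturn), decel_door = avg(ddoor),
               accel_start = avg(astart), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, summ)
  tests <- list()
  for (m in c("speed", "decel_stop", "decel_turn", "decel_door",
              "accel_start")) {
    x <- per[per$group == "PD", m]; y <- per[per$group == "HC", m]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) >= 2 && length(y) >= 2) {
      tst <- stats::t.test(x, y)
      tests[[length(tests) + 1L]] <- data.frame(
        measure = m, comparison = "PD_vs_HC", t = unname(tst$statistic),
        p = tst$p.value, mean_pd = mean(x), mean_hc = mean(y))
    }
  }
  for (g in c("PD", "HC")) {
    x <- per[per$group == g, "decel_door"]
    x <- x[is.finite(x)]
    if (length(x) >= 2) {
      tst <- stats::t.test(x, mu = 0)
      tests[[length(tests) + 1L]] <- data.frame(
        measure = "decel_door", comparison = paste0(g, "_vs_0"),
        t = unname(tst$statistic), p = tst$p.value,
        mean_pd = if (g == "PD") mean(x) else NA,
        mean_hc = if (g == "HC") mean(x) else NA)
    }
  }
  list(per_participant = per, tests = do.call(rbind, tests))
}
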