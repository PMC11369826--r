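#' Gait-protocol specification
#'
#' Parameters of the synthetic overground gait task: per run, 60 s of
#' initial quiet standing, then continuous walking up and down a corridor
#' with a doorway halfway and 180-degree turns at the ends, ~20 s walking
#' legs between consecutive door/turn arrivals, and an instructed 30 s stop
#' every fifth arrival (i.e. every 2.5 corridor lengths), with turn
#' directions alternating and switching after each stop. Freezing episodes
#' are attached to their trigger events at the given per-trigger rates with
#' log-normal durations (median 3.8 s).
#'
#' @param n_runs Number of runs (4).
#' @param run_length_s Run duration in seconds (~6.5 min).
#' @param initial_stand_s Quiet standing at run start (s).
#' @param walk_leg_s Walking time between consecutive arrivals (s).
#' @param stop_duration_s Instructed stop duration (s).
#' @param stop_every Arrivals per stop cycle (5 = 2.5 corridor lengths).
#' @param freeze_rates Named per-trigger freeze probabilities
#'   (turn/doorway/start/destination/walking).
#' @param freeze_meanlog,freeze_sdlog Log-normal freeze-duration
#'   parameters (median `exp(meanlog)` = 3.8 s).
#' @param freeze_min_s,freeze_max_s Truncation bounds for freeze durations.
#' @param turn_duration_s Walking-turn duration baseline (s); the
#'   participant's group scales it.
#' @param midstop_turn_at_s Time into a square stop at which the
#'   instructed 180-degree turn happens.
#' @return A list of class `"protocol_spec"`.
#' @export
protocolSpec <- function(n_runs = 4, run_length_s = 390,
                         initial_stand_s = 60, walk_leg_s = 20,
                         stop_duration_s = 30, stop_every = 5,
                         freeze_rates = c(turn = 0.35, doorway = 0.25,
                                          start = 0.12, destination = 0.12,
                                          walking = 0.04),
                         freeze_meanlog = log(3.8), freeze_sdlog = 1.0,
                         freeze_min_s = 0.4, freeze_max_s = 45,
                         turn_duration_s = 2.5, midstop_turn_at_s = 15) {
  spec <- as.list(environment())
  class(spec) <- "protocol_spec"
  spec
}

#' Participant metadata for the synthetic generator
#'
#' @param id Participant identifier.
#' @param group `"PD"` (freezer) or `"HC"` (healthy control).
#' @param age Age in years (drives the DPF).
#' @param fog_severity Multiplier in `[0, 1+]` on the spec's freeze rates
#'   (0 for HC).
#' @param updrs Motor-score covariate carried into the severity model.
#' @param cruise_speed Comfortable walking speed, m/s (group means 0.95 PD
#'   / 1.09 HC).
#' @param turn_duration_s Time to complete a 180-degree turn (3.07 PD /
#'   1.89 HC).
#' @param decel_window_s Deceleration time approaching a stop (longer for
#'   PD, giving the group's slower pre-stop deceleration).
#' @param ramp_s Time to reach cruise speed after a start.
#' @return List of class `"participant_meta"`.
#' @export
participantMeta <- function(id = "sub-01", group = c("PD", "HC"), age = 66,
                            fog_severity = if (group[1] == "PD") 1 else 0,
                            updrs = if (group[1] == "PD") 44 else 0,
                            cruise_speed = if (group[1] == "PD") 0.95
                                           else 1.09,
                            turn_duration_s = if (group[1] == "PD") 3.07
                                              else 1.89,
                            decel_window_s = if (group[1] == "PD") 4 else 3,
                            ramp_s = if (group[1] == "PD") 5 else 3.5) {
  group <- match.arg(group)
  meta <- list(id = id, group = group, age = age,
               fog_severity = fog_severity, updrs = updrs,
               cruise_speed = cruise_speed,
               turn_duration_s = turn_duration_s,
               decel_window_s = decel_window_s, ramp_s = ramp_s)
  class(meta) <- "participant_meta"
  meta
}

#' Ground-truth specification for the synthetic forward model
#'
#' Defines everything the generator knows and the pipeline must recover:
#' true event-locked response amplitudes per (condition, ROI) on the
#' z-unit scale, canonical-HRF parameters, the low-rank systemic confound
#' structure shared between long and short channels, head-pitch coupling
#' gains (indirect movement artifact), direct spike/shift artifact rates,
#' the optional freeze-locked systemic surge, and measurement noise.
#'
#' @param roi_amplitudes Conditions x ROI matrix of true response
#'   amplitudes (z-units). Default reflects plausible motor/prefrontal
#'   patterns during stopping, starting, turning, doorway passage and
#'   freezing (freezing: reduced PFC, elevated SMA).
#' @param hb_per_z Micromolar HbO per z-unit of amplitude.
#' @param hbr_ratio HbR amplitude as a fraction of HbO for the neural
#'   response (-1/3).
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio Canonical HRF parameters.
#' @param systemic_rank Number of systemic components k (<= 8).
#' @param systemic_amps_uM Micromolar amplitude of each systemic component
#'   (recycled to `systemic_rank`); 0 disables systemic confounds.
#' @param sys_hbr_share HbR share of non-neural (systemic/movement)
#'   signal.
#' @param short_scalp_gain Loading multiplier for short channels (scalp
#'   share).
#' @param coupling_mean_uM_deg,coupling_sd_uM_deg Per-channel head-pitch
#'   coupling gains, micromolar per degree; 0/0 disables.
#' @param freeze_surge_uM Amplitude of the heart-rate-like systemic surge
#'   time-locked to freeze onsets; 0 disables.
#' @param noise_od_sd White measurement noise (OD units).
#' @param p_spike,p_shift Per turn/freeze probability of a direct spike /
#'   baseline-shift artifact.
#' @param spike_amp_od,shift_amp_od Ranges (length 2) of artifact
#'   amplitudes in OD.
#' @return List of class `"ground_truth_spec"`.
#' @export
groundTruth <- function(roi_amplitudes = NULL, hb_per_z = 0.3,
                        hbr_ratio = -1 / 3,
                        hrf_peak_s = 6, hrf_undershoot_s = 16,
                        hrf_ratio = 1 / 6,
                        systemic_rank = 8,
                        systemic_amps_uM = c(0.4, 0.2, 0.15, 0.1, 0.08,
                                             0.08, 0.08, 0.08),
                        sys_hbr_share = 0.5, short_scalp_gain = 1.2,
                        coupling_mean_uM_deg = 0.02,
                        coupling_sd_uM_deg = 0.006,
                        freeze_surge_uM = 0.5, noise_od_sd = 0.0015,
                        p_spike = 0.15, p_shift = 0.1,
                        spike_amp_od = c(0.1, 0.4),
                        shift_amp_od = c(0.05, 0.15)) {
  if (is.null(roi_amplitudes)) {
    rois <- c("M1", "PMC", "SMA", "PFC", "PPC")
    roi_amplitudes <- rbind(
      stop    = c(-0.20, 0.10, 0.25, 0.25, 0.00),
      start   = c(-0.15, -0.17, 0.00, 0.00, 0.00),
      turn    = c(0.10, 0.17, 0.12, 0.05, 0.05),
      doorway = c(0.05, 0.10, 0.05, 0.10, 0.05),
      freeze  = c(0.00, 0.10, 0.15, -0.25, 0.00))
    colnames(roi_amplitudes) <- rois
  }
  if (any(!is.finite(roi_amplitudes)))
    stop("roi_amplitudes must be finite")
  if (systemic_rank > 8) stop("systemic_rank must be <= 8")
  tr <- as.list(environment())
  tr$systemic_amps_uM <- rep_len(systemic_amps_uM, max(systemic_rank, 1L))
  class(tr) <- "ground_truth_spec"
  tr
}

#' Generate the protocol event schedule
#'
#' Deterministic task structure (stand/start/door/turn/stop arrivals, turn
#' directions alternating and switching after each stop) plus seeded
#' random freeze attachment per trigger. Doorway crossings that follow a
#' door-front stop are provisionally placed 1 s after the resume start and
#' refined by [generateSession()] to the synthetic walker's actual
#' door-plane crossing.
#'
#' @param spec A [protocolSpec()].
#' @param seed Integer seed; two calls with the same seed are identical.
#' @param fog_severity Multiplier on the spec freeze rates.
#' @return An event table (all runs, `source = "protocol"`).
#' @export
generateProtocol <- function(spec = protocolSpec(), seed = 1,
                             fog_severity = 1) {
  .withSeed(.childSeed(seed, 1L), {
    rows <- list()
    for (r in seq_len(spec$n_runs)) {
      run <- sprintf("run-%02d", r)
      sched <- .runSchedule(spec, r)
      sched$run <- run
      fz <- .attachFreezes(sched, spec, fog_severity)
      if (nrow(fz)) fz$run <- run
      rows[[r]] <- rbind(sched, fz)
    }
    all <- do.call(rbind, rows)
    eventTable(onset = all$onset, duration = all$duration, type = all$type,
               trigger = all$trigger, source = "protocol", run = all$run)
  })
}

# deterministic arrival schedule for one run
.runSchedule <- function(spec, run_index) {
  ev <- data.frame(onset = 0, duration = spec$initial_stand_s,
                   type = "stand", trigger = "none",
                   stringsAsFactors = FALSE)
  add <- function(onset, duration, type, trigger = "none")
    rbind(ev, data.frame(onset = onset, duration = duration, type = type,
                         trigger = trigger, stringsAsFactors = FALSE))
  t <- spec$initial_stand_s
  ev <- add(t, 0, "start")
  # turn direction alternates; initial direction alternates across runs
  dirLeft <- (run_index %% 2L) == 1L
  arrival <- "door"   # first arrival after the starting square is the door
  count <- 0L
  repeat {
    t <- t + spec$walk_leg_s
    if (t > spec$run_length_s - 1) break
    count <- count + 1L
    isStop <- (count %% spec$stop_every) == 0L &&
      (t + spec$stop_duration_s) <= spec$run_length_s
    if (isStop) {
      ev <- add(t, spec$stop_duration_s, "stop",
                if (arrival == "door") "doorway" else "turn")
      if (arrival == "end") {
        # stop in the square: instructed 180-degree turn halfway through
        ev <- add(t + spec$midstop_turn_at_s, 1.5,
                  if (dirLeft) "turn_left" else "turn_right")
        dirLeft <- !dirLeft
      }
      dirLeft <- !dirLeft        # direction switch after each stop
      t <- t + spec$stop_duration_s
      ev <- add(t, 0, "start")
      if (arrival == "door") {
        # stopped in front of the door; crossing just after resuming
        # (placeholder; session generation refines it kinematically)
        ev <- add(t + 1, 1, "doorway")
      }
    } else if (arrival == "door") {
      ev <- add(t, 1, "doorway")
    } else {
      ev <- add(t, spec$turn_duration_s,
                if (dirLeft) "turn_left" else "turn_right")
      dirLeft <- !dirLeft
    }
    arrival <- if (arrival == "door") "end" else "door"
  }
  ev[order(ev$onset), , drop = FALSE]
}

# seeded freeze attachment to trigger events (caller manages RNG state)
.attachFreezes <- function(sched, spec, fog_severity) {
  rates <- spec$freeze_rates * fog_severity
  out <- list()
  rdur <- function() min(max(stats::rlnorm(1, spec$freeze_meanlog,
                                           spec$freeze_sdlog),
                             spec$freeze_min_s), spec$freeze_max_s)
  for (i in seq_len(nrow(sched))) {
    ty <- sched$type[i]; on <- sched$onset[i]
    cand <- NULL
    if (ty %in% c("turn_left", "turn_right") &&
        stats::runif(1) < rates[["turn"]])
      cand <- c(on + stats::runif(1, 0, 0.5), "turn")
    else if (ty == "doorway" && stats::runif(1) < rates[["doorway"]])
      cand <- c(max(0, on - stats::runif(1, 0.2, 0.8)), "doorway")
    else if (ty == "start" && stats::runif(1) < rates[["start"]])
      cand <- c(on + stats::runif(1, 0, 0.5), "start")
    else if (ty == "stop" && stats::runif(1) < rates[["destination"]])
      cand <- c(max(0, on - stats::runif(1, 1, 3)), "destination")
    if (!is.null(cand))
      out[[length(out) + 1L]] <- data.frame(
        onset = as.numeric(cand[1]), duration = rdur(), type = "freeze",
        trigger = cand[2], stringsAsFactors = FALSE)
    # walking freezes: chance per leg, placed mid-leg
    if (ty %in% c("doorway", "turn_left", "turn_right") &&
        stats::runif(1) < rates[["walking"]]) {
      legmid <- on - spec$walk_leg_s / 2
      out[[length(out) + 1L]] <- data.frame(
        onset = max(0, legmid + stats::runif(1, -3, 3)), duration = rdur(),
        type = "freeze", trigger = "walking", stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(onset = numeric(), duration = numeric(),
                      type = character(), trigger = character(),
                      stringsAsFactors = FALSE))
  fz <- do.call(rbind, out)
  fz <- fz[order(fz$onset), , drop = FALSE]
  # drop freezes overlapping an earlier one or spilling past the run
  keep <- rep(TRUE, nrow(fz)); lastEnd <- -Inf
  for (i in seq_len(nrow(fz))) {
    if (fz$onset[i] < lastEnd + 1 ||
        fz$onset[i] + fz$duration[i] > spec$run_length_s - 1) {
      keep[i] <- FALSE
    } else lastEnd <- fz$onset[i] + fz$duration[i]
  }
  fz[keep, , drop = FALSE]
}
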