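#' Generate a complete synthetic session with known ground truth
#'
#' Realizes the forward model for one participant: per run, raw
#' dual-wavelength intensities (50 Hz) built as
#' forward-MBLL(neural HRF responses + head-pitch-coupled component)
#' + low-rank systemic confounds shared with the short channels
#' + freeze-locked systemic surge + direct spike/shift artifacts
#' + white noise, together with 60 Hz kinematics consistent with the
#' protocol, two raters' freeze annotations (rater B = rater A jittered
#' within the merge tolerance), the protocol event table, and the
#' realized ground truth (loadings, coupling gains, artifact times, and
#' the noiseless neural time courses on the 60 Hz analysis grid).
#'
#' Short channels receive the systemic components, the surge and a scalp
#' share of the movement coupling, but no neural term.
#'
#' @param spec A [protocolSpec()].
#' @param truth A [groundTruth()] specification.
#' @param meta A [participantMeta()].
#' @param seed Integer seed; the session is reproducible from it.
#' @return List of class `"fog_session"`: `montage`, `runs` (per run:
#'   `recording` raw intensity + `kinematics`), `events` (protocol),
#'   `raterA`, `raterB`, `truth` (realized), `meta`, `seed`.
#' @examples
#' \donttest{
#' s <- generateSession(protocolSpec(n_runs = 1, run_length_s = 200),
#'                      seed = 7)
#' s$runs[["run-01"]]$recording
#' }
#' @export
generateSession <- function(spec = protocolSpec(), truth = groundTruth(),
                            meta = participantMeta(), seed = 1) {
  if (any(!is.finite(truth$roi_amplitudes)))
    stop("roi_amplitudes must be finite")
  montage <- defaultMontage()
  events <- generateProtocol(spec, seed, meta$fog_severity)
  .withSeed(.childSeed(seed, 2L), {
    ch <- montage@channels
    k <- truth$systemic_rank
    loadings <- matrix(stats::runif(nrow(ch) * k, 0.5, 1.5), nrow(ch), k,
                       dimnames = list(ch$id, NULL))
    loadings <- sweep(loadings, 2, rep_len(truth$systemic_amps_uM, k), `*`)
    loadings[ch$kind == "short", ] <-
      loadings[ch$kind == "short", ] * truth$short_scalp_gain
    coupling <- stats::rnorm(nrow(ch), truth$coupling_mean_uM_deg,
                             truth$coupling_sd_uM_deg)
    names(coupling) <- ch$id
    # the freeze surge is a transient of the blood-pressure-like systemic
    # component, so it expresses through that component's channel loadings
    # (scalp and cortex alike) rather than an independent direction
    surge_gain <- if (k >= 3 && any(loadings[, 3] != 0)) {
      loadings[, 3] / mean(loadings[, 3]) * truth$freeze_surge_uM
    } else rep(truth$freeze_surge_uM, nrow(ch))
    names(surge_gain) <- ch$id
    intensity0 <- stats::runif(nrow(ch) * 2, 0.5, 2)

    runs <- list(); artifacts <- list(); neuralZ <- list()
    for (r in unique(events$run)) {
      ev <- events[events$run == r, , drop = FALSE]
      kin <- .runKinematics(ev, spec, meta)
      n60 <- nSamples(kin)
      amps <- truth$roi_amplitudes
      neuralZ[[r]] <- neuralTimecourses(ev, amps, samplingRate(kin), n60,
                                        truth$hrf_peak_s,
                                        truth$hrf_undershoot_s,
                                        truth$hrf_ratio)
      fn <- .runFnirs(ev, spec, truth, meta, montage, kin,
                      loadings, coupling, surge_gain, intensity0, r)
      runs[[r]] <- list(recording = fn$recording, kinematics = kin)
      artifacts[[r]] <- fn$artifacts
    }
    raters <- .raterTables(events, spec)
    out <- list(
      montage = montage, runs = runs, events = events,
      raterA = raters$A, raterB = raters$B,
      truth = list(spec = truth, roi_amplitudes = truth$roi_amplitudes,
                   loadings = loadings, coupling = coupling,
                   surge_gain = surge_gain,
                   artifact_times = do.call(rbind, artifacts),
                   neural_z = neuralZ, seed = seed),
      meta = meta, seed = seed)
    class(out) <- "fog_session"
    out
  })
}

# 60 Hz kinematics consistent with one run's event table
.runKinematics <- function(ev, spec, meta, fs = 60) {
  n <- round(spec$run_length_s * fs)
  t <- (seq_len(n) - 1) / fs
  vc <- meta$cruise_speed
  idx <- function(a, b) {  # sample indices for [a, b)
    lo <- max(1L, 1L + floor(a * fs)); hi <- min(n, ceiling(b * fs))
    if (lo > hi) integer() else lo:hi
  }
  halts <- ev[ev$type %in% c("stand", "stop", "freeze"), , drop = FALSE]
  turnsW <- ev[ev$type %in% c("turn_left", "turn_right"), , drop = FALSE]
  doors <- ev[ev$type == "doorway", , drop = FALSE]
  stops <- ev[ev$type == "stop", , drop = FALSE]

  v <- rep(vc, n)
  # turning slows the walker; slight anticipatory slowing before turns/doors
  for (i in seq_len(nrow(turnsW))) {
    o <- turnsW$onset[i]; d <- max(turnsW$duration[i], 1)
    ii <- idx(o - 2, o)
    if (length(ii)) v[ii] <- v[ii] * seq(1, 0.85, length.out = length(ii))
    ii <- idx(o, o + d)
    if (length(ii))
      v[ii] <- v[ii] * (0.55 + 0.45 * abs(cos(pi * seq_along(ii) /
                                                length(ii))))
  }
  if (meta$group == "PD") {
    for (o in doors$onset) {
      ii <- idx(o - 2, o)
      if (length(ii)) v[ii] <- v[ii] * seq(1, 0.92, length.out = length(ii))
    }
  }
  # deceleration into instructed stops: slow approach, sharp final halt
  for (o in stops$onset) {
    dw <- meta$decel_window_s
    ii <- idx(o - dw, o - 0.15)
    if (length(ii)) v[ii] <- seq(vc, 0.3, length.out = length(ii))
    ii <- idx(o - 0.15, o)
    if (length(ii)) v[ii] <- seq(0.3, 0, length.out = length(ii))
  }
  # freezes halt abruptly
  for (i in seq_len(nrow(halts))) {
    a <- halts$onset[i]
    if (halts$type[i] == "freeze") {
      ii <- idx(a - 0.3, a)
      if (length(ii)) v[ii] <- v[ii] * seq(1, 0, length.out = length(ii))
    }
  }
  for (i in seq_len(nrow(halts)))
    v[idx(halts$onset[i], halts$onset[i] + halts$duration[i])] <- 0
  # resuming gait: quick first step then ramp to cruise
  for (i in seq_len(nrow(halts))) {
    b <- halts$onset[i] + halts$duration[i]
    if (b >= spec$run_length_s - 0.5) next
    later <- halts$onset > b & halts$onset < b + meta$ramp_s + 0.5
    ii <- idx(b, b + 0.3)
    if (length(ii)) v[ii] <- seq(0, 0.45 * vc, length.out = length(ii))
    ii <- idx(b + 0.3, b + meta$ramp_s)
    if (length(ii) && !any(later))
      v[ii] <- seq(0.45 * vc, vc, length.out = length(ii))
  }
  for (i in seq_len(nrow(halts)))  # halts win over overlapping ramps
    v[idx(halts$onset[i], halts$onset[i] + halts$duration[i])] <- 0
  v <- .movAvg(v, round(0.25 * fs))
  bounce <- 0.03 * sin(2 * pi * 1.9 * t) * (v > 0.3)
  # measurement noise is smaller when standing (otherwise clipping at zero
  # would make the standing walker creep forward)
  v <- pmax(0, v + bounce + stats::rnorm(n, 0, 0.004 + 0.01 * (v > 0.1)))

  # yaw: 180-degree transitions at every turn event (trapezoidal rate)
  yaw <- numeric(n); cur <- 0
  allTurns <- ev[ev$type %in% c("turn_left", "turn_right"), , drop = FALSE]
  for (i in seq_len(nrow(allTurns))) {
    o <- allTurns$onset[i]
    d <- max(allTurns$duration[i], 1.2)
    sgn <- if (allTurns$type[i] == "turn_left") 1 else -1
    ii <- idx(o, o + d)
    if (!length(ii)) next
    # rate ramps up over 0.15 s, holds, ramps down
    m <- length(ii); ramp <- max(2L, round(0.15 * fs))
    prof <- c(seq(0, 1, length.out = ramp),
              rep(1, max(0, m - 2 * ramp)),
              seq(1, 0, length.out = ramp))[seq_len(m)]
    step <- 180 * prof / sum(prof)
    yaw[ii] <- cur + cumsum(sgn * step)
    cur <- cur + sgn * 180
    if (max(ii) < n) yaw[(max(ii) + 1L):n] <- cur
  }

  # position: anchor events to corridor geometry, interpolate by the
  # normalized cumulative velocity so halts freeze the position
  L <- 2 * vc * spec$walk_leg_s
  anchors <- .positionAnchors(ev, spec, L)
  x <- numeric(n)
  cv <- cumsum(v) / fs
  for (i in seq_len(nrow(anchors))) {
    i0 <- min(n, 1L + round(anchors$time[i] * fs))
    x[i0] <- anchors$x[i]
    if (i < nrow(anchors)) {
      i1 <- min(n, 1L + round(anchors$time[i + 1] * fs))
      if (i1 > i0 + 1L) {
        seg <- (i0 + 1L):i1
        prog <- cv[seg] - cv[i0]
        tot <- prog[length(prog)]
        if (tot > 0) x[seg] <- anchors$x[i] +
            (anchors$x[i + 1] - anchors$x[i]) * prog / tot
        else x[seg] <- anchors$x[i]
      } else if (i1 > i0) x[(i0 + 1L):i1] <- anchors$x[i + 1]
    } else if (i0 < n) {
      seg <- (i0 + 1L):n
      h <- anchors$heading[i]
      x[seg] <- pmin(L, pmax(0, anchors$x[i] + h * (cv[seg] - cv[i0])))
    }
  }
  if (nrow(anchors)) {
    first <- 1L + round(anchors$time[1] * fs)
    if (first > 1L) x[seq_len(first - 1L)] <- anchors$x[1]
  }

  # head pitch: looking down around stops, turns, doors and freezes
  pitch <- numeric(n)
  bump <- function(o, d, amp) {
    ii <- idx(o - 1, o + d + 1)
    if (!length(ii)) return()
    m <- length(ii)
    prof <- sin(pi * seq_len(m) / (m + 1))^2
    pitch[ii] <<- pitch[ii] + amp * prof
  }
  for (i in seq_len(nrow(halts)))
    bump(halts$onset[i], halts$duration[i],
         if (halts$type[i] == "freeze") 15 else 12)
  for (i in seq_len(nrow(turnsW)))
    bump(turnsW$onset[i], turnsW$duration[i], 10)
  for (o in doors$onset) bump(o - 1, 1.5, 6)
  pitch <- .movAvg(pitch + stats::rnorm(n, 0, 0.3), round(0.5 * fs))

  acc_x <- c(0, diff(v)) * fs + 0.4 * sin(2 * pi * 1.9 * t) * (v > 0.3) +
    stats::rnorm(n, 0, 0.05)
  acc_y <- 0.3 * sin(2 * pi * 0.95 * t) * (v > 0.3) + stats::rnorm(n, 0, 0.05)
  acc_z <- 0.5 * sin(2 * pi * 1.9 * t + 0.5) * (v > 0.3) +
    stats::rnorm(n, 0, 0.05)
  yawrate <- c(0, diff(yaw)) * fs                      # deg/s
  ang_z <- c(0, diff(yawrate)) * fs * pi / 180 +       # rad/s^2
    stats::rnorm(n, 0, 0.05)
  ang_x <- stats::rnorm(n, 0, 0.05) + 0.1 * sin(2 * pi * 1.9 * t) * (v > 0.3)
  ang_y <- stats::rnorm(n, 0, 0.05)

  dat <- cbind(accel_x = acc_x, accel_y = acc_y, accel_z = acc_z,
               angacc_x = ang_x, angacc_y = ang_y, angacc_z = ang_z,
               neck_pitch = pitch,
               neck_roll = stats::rnorm(n, 0, 0.3),
               neck_yaw = 0.1 * yaw + stats::rnorm(n, 0, 0.3),
               velocity = v, pos_x = x,
               pos_y = stats::rnorm(n, 0, 0.05))
  gaitKinematics(dat, fs = fs, time0 = 0)
}

# corridor anchor positions for door/turn/stop events
.positionAnchors <- function(ev, spec, L) {
  d <- L / 2
  h <- 1
  anc <- list(data.frame(time = 0, x = 0, heading = 1))
  evs <- ev[order(ev$onset), , drop = FALSE]
  for (i in seq_len(nrow(evs))) {
    ty <- evs$type[i]; o <- evs$onset[i]
    if (ty == "doorway") {
      anc[[length(anc) + 1L]] <- data.frame(time = o, x = d, heading = h)
    } else if (ty %in% c("turn_left", "turn_right")) {
      # walking turn happens at a corridor end; mid-stop turns only flip
      # the heading (position already anchored by the stop)
      endx <- if (h > 0) L else 0
      isMidStop <- any(evs$type == "stop" &
                         o > evs$onset & o < evs$onset + evs$duration)
      if (!isMidStop)
        anc[[length(anc) + 1L]] <- data.frame(time = o, x = endx,
                                              heading = -h)
      h <- -h
    } else if (ty == "stop") {
      if (evs$trigger[i] == "doorway") {
        anc[[length(anc) + 1L]] <- data.frame(time = o, x = d - 0.5 * h,
                                              heading = h)
      } else {
        endx <- if (h > 0) L else 0
        anc[[length(anc) + 1L]] <- data.frame(time = o, x = endx,
                                              heading = h)
      }
    }
  }
  out <- do.call(rbind, anc)
  out$heading <- c(out$heading[-1], out$heading[nrow(out)])
  out
}

# forward fNIRS model for one run; returns raw-intensity recording
.runFnirs <- function(ev, spec, truth, meta, montage, kin,
                      loadings, coupling, surge_gain, intensity0, run,
                      fs = 50) {
  ch <- montage@channels
  n <- round(spec$run_length_s * fs)
  t <- (seq_len(n) - 1) / fs
  isLong <- ch$kind == "long"

  # neural term (long channels only), micromolar
  neural <- neuralTimecourses(ev, truth$roi_amplitudes, fs, n,
                              truth$hrf_peak_s, truth$hrf_undershoot_s,
                              truth$hrf_ratio)
  hboN <- matrix(0, nrow(ch), n, dimnames = list(ch$id, NULL))
  for (i in which(isLong)) {
    roi <- ch$roi[i]
    if (roi %in% rownames(neural))
      hboN[i, ] <- truth$hb_per_z * neural[roi, ]
  }

  # head-pitch coupling (indirect movement artifact), all channels
  kin60 <- channelData(kin)[, "neck_pitch"]
  t60 <- (seq_along(kin60) - 1) / samplingRate(kin)
  pitch <- stats::approx(t60, kin60, xout = t, rule = 2)$y
  pitch <- pitch - stats::median(pitch)
  hboK <- outer(coupling, pitch)

  # low-rank systemic components, shared across channels
  k <- truth$systemic_rank
  sysM <- matrix(0, nrow(ch), n)
  if (k > 0 && any(truth$systemic_amps_uM != 0)) {
    comps <- .systemicComponents(k, n, fs)
    sysM <- loadings[, seq_len(k), drop = FALSE] %*% comps
  }

  # freeze-locked systemic surge (heart-rate-like transient)
  surge <- numeric(n)
  fz <- ev[ev$type == "freeze", , drop = FALSE]
  if (truth$freeze_surge_uM != 0 && nrow(fz)) {
    kern <- stats::dgamma(seq(0, 15, by = 1 / fs), shape = 5, rate = 5 / 4)
    kern <- kern / max(kern)
    imp <- numeric(n)
    ii <- 1L + round(fz$onset * fs)
    imp[ii[ii <= n]] <- 1
    surge <- stats::convolve(imp, rev(kern), type = "open")[seq_len(n)]
  }
  hboS <- outer(unname(surge_gain), surge)

  hbo <- hboN + hboK + sysM + hboS
  hbr <- truth$hbr_ratio * hboN +
    truth$sys_hbr_share * (hboK + sysM + hboS)

  dat <- matrix(0, 2L * nrow(ch), n)
  ord <- as.vector(rbind(seq_len(nrow(ch)) * 2L - 1L, seq_len(nrow(ch)) * 2L))
  dat[seq(1, nrow(dat), by = 2), ] <- hbo
  dat[seq(2, nrow(dat), by = 2), ] <- hbr
  rownames(dat) <- as.vector(rbind(paste0(ch$id, "@HbO"),
                                   paste0(ch$id, "@HbR")))
  hbRec <- fnirsRecording(dat, fs = fs, unit = "micromolar",
                          channel = rep(ch$id, each = 2),
                          chromophore = rep(c("HbO", "HbR"), nrow(ch)),
                          runId = run)
  od <- hbToOd(hbRec, montage, age_years = meta$age)

  # direct movement artifacts: spikes and transient baseline shifts,
  # time-locked to turns and freezes, long channels only
  arts <- list()
  trig <- ev[ev$type %in% c("turn_left", "turn_right", "freeze"), ,
             drop = FALSE]
  longIds <- ch$id[isLong]
  for (i in seq_len(nrow(trig))) {
    o <- trig$onset[i]
    if (stats::runif(1) < truth$p_spike) {
      cid <- sample(longIds, 1)
      a <- stats::runif(1, truth$spike_amp_od[1], truth$spike_amp_od[2])
      dur <- stats::runif(1, 0.3, 1)
      at <- o + stats::runif(1, 0, 1)
      ii <- (1L + round(at * fs)):min(n, round((at + dur) * fs))
      shape <- sin(pi * seq_along(ii) / (length(ii) + 1))
      rows <- which(od@channel == cid)
      od@data[rows[1], ii] <- od@data[rows[1], ii] + a * shape
      od@data[rows[2], ii] <- od@data[rows[2], ii] + 0.8 * a * shape
      arts[[length(arts) + 1L]] <- data.frame(run = run, time = at,
                                              kind = "spike", channel = cid,
                                              amplitude = a)
    }
    if (stats::runif(1) < truth$p_shift) {
      cid <- sample(longIds, 1)
      a <- stats::runif(1, truth$shift_amp_od[1], truth$shift_amp_od[2])
      dur <- stats::runif(1, 2, 5)
      at <- o + stats::runif(1, 0, 1)
      ii <- (1L + round(at * fs)):min(n, round((at + dur) * fs))
      rows <- which(od@channel == cid)
      od@data[rows[1], ii] <- od@data[rows[1], ii] + a
      od@data[rows[2], ii] <- od@data[rows[2], ii] + 0.8 * a
      arts[[length(arts) + 1L]] <- data.frame(run = run, time = at,
                                              kind = "shift", channel = cid,
                                              amplitude = a)
    }
  }
  if (truth$noise_od_sd > 0)
    od@data <- od@data + matrix(stats::rnorm(length(od@data), 0,
                                             truth$noise_od_sd),
                                nrow(od@data))

  inten <- intensity0 * 10^(-od@data)
  rownames(inten) <- rownames(od@data)
  rec <- fnirsRecording(inten, fs = fs, unit = "raw_intensity",
                        channel = od@channel, wavelength = od@wavelength,
                        chromophore = rep("n/a", nrow(inten)),
                        runId = run)
  arts <- if (length(arts)) do.call(rbind, arts) else
    data.frame(run = character(), time = numeric(), kind = character(),
               channel = character(), amplitude = numeric())
  list(recording = rec, artifacts = arts)
}

# k standardized systemic component time courses (drift, very-low-
# frequency, Mayer ~0.1 Hz, respiration ~0.25 Hz, cardiac ~1.2 Hz, plus
# band-limited noise components)
.systemicComponents <- function(k, n, fs) {
  t <- (seq_len(n) - 1) / fs
  smoothNoise <- function(cut_s) {
    knots <- seq(0, t[n], by = cut_s)
    vals <- cumsum(stats::rnorm(length(knots)))
    out <- stats::spline(knots, vals, xout = t)$y
    .ztrans(out)
  }
  oscil <- function(f) {
    ph <- stats::runif(1, 0, 2 * pi)
    am <- 1 + 0.3 * smoothNoise(20)
    .ztrans(am * sin(2 * pi * f * t + ph +
                       0.5 * smoothNoise(30)))
  }
  comps <- list(smoothNoise(30),        # slow drift
                oscil(0.04),            # very low frequency
                oscil(0.1),             # Mayer waves
                oscil(0.25),            # respiration
                oscil(1.2),             # cardiac
                smoothNoise(8), smoothNoise(5), smoothNoise(12))
  do.call(rbind, comps[seq_len(k)])
}

# two raters' freeze annotations: A jitters the truth slightly, B jitters
# A within the merge tolerance
.raterTables <- function(events, spec) {
  fz <- events[events$type == "freeze", , drop = FALSE]
  mk <- function(onset, duration, source) {
    keep <- duration > 0.2
    eventTable(onset = pmax(0, onset[keep]), duration = duration[keep],
               type = "freeze", trigger = fz$trigger[keep], source = source,
               run = fz$run[keep])
  }
  if (!nrow(fz))
    return(list(A = mk(numeric(), numeric(), "rater_A"),
                B = mk(numeric(), numeric(), "rater_B")))
  onA <- fz$onset + stats::rnorm(nrow(fz), 0, 0.15)
  duA <- pmax(0.3, fz$duration * exp(stats::rnorm(nrow(fz), 0, 0.1)))
  onB <- onA + stats::runif(nrow(fz), -0.9, 0.9)
  duB <- pmax(0.3, duA * exp(stats::rnorm(nrow(fz), 0, 0.15)))
  list(A = mk(onA, duA, "rater_A"), B = mk(onB, duB, "rater_B"))
}

#' @export
print.fog_session <- function(x, ...) {
  cat("Synthetic fNIRS gait session:", x$meta$id, sprintf("(%s)", x$meta$group),
      "|", length(x$runs), "runs | seed", x$seed, "\n")
  cat("  ", sum(x$events$type == "freeze"), "freezes;",
      nrow(x$truth$artifact_times), "direct artifacts\n")
  invisible(x)
}

#' Ground-truth neural recording for one run
#'
#' Materializes the session's noiseless ROI-level neural time courses
#' (z-amplitude scale, 60 Hz analysis grid) as a recording, so the epoch
#' pipeline can be applied identically to truth and estimate in recovery
#' tests.
#'
#' @param session A `"fog_session"` from [generateSession()].
#' @param run Run id (e.g. `"run-01"`).
#' @return A [FnirsRecording-class] with one HbO row per ROI
#'   (ids `"<ROI>@HbO"`), `unit = "zscore"`.
#' @export
truthRecording <- function(session, run) {
  nz <- session$truth$neural_z[[run]]
  if (is.null(nz)) stop("unknown run: ", run)
  rown <- paste0(rownames(nz), "@HbO")
  dat <- nz
  rownames(dat) <- rown
  fnirsRecording(dat, fs = 60, unit = "zscore", channel = rownames(nz),
                 chromophore = rep("HbO", nrow(dat)), runId = run)
}

#' Generate a synthetic cohort
#'
#' Draws participant metadata (ages, walking speeds, freeze severities,
#' motor scores) for a PD group of freezers and a healthy-control group,
#' and generates one session per participant. For modest cohorts only --
#' sessions are kept in memory; [runPipeline()] streams participants
#' instead when processing larger cohorts.
#'
#' @param n_pd,n_hc Group sizes.
#' @param spec,truth Shared [protocolSpec()] / [groundTruth()].
#' @param seed Integer seed.
#' @param severity_slope If nonzero, couples each PD participant's PFC
#'   doorway amplitude to their standardized freeze severity with this
#'   slope (used by severity-model recovery tests).
#' @return List of `"fog_session"` objects.
#' @export
generateCohort <- function(n_pd = 4, n_hc = 4, spec = protocolSpec(),
                           truth = groundTruth(), seed = 1,
                           severity_slope = 0) {
  metas <- .withSeed(.childSeed(seed, 99L), {
    sev <- pmax(0.2, stats::rnorm(n_pd, 1, 0.35))
    lapply(seq_len(n_pd + n_hc), function(i) {
      pd <- i <= n_pd
      participantMeta(
        id = sprintf("sub-%02d", i), group = if (pd) "PD" else "HC",
        age = round(stats::rnorm(1, 66, 9)),
        fog_severity = if (pd) sev[i] else 0,
        updrs = if (pd) round(stats::rnorm(1, 43.7, 10.5)) else 0,
        cruise_speed = stats::rnorm(1, if (pd) 0.95 else 1.09, 0.07),
        turn_duration_s = max(1.2, stats::rnorm(1, if (pd) 3.07 else 1.89,
                                                0.3)))
    })
  })
  sevs <- vapply(metas[seq_len(n_pd)], `[[`, 0, "fog_severity")
  zsev <- if (n_pd > 1) .ztrans(sevs) else rep(0, n_pd)
  lapply(seq_along(metas), function(i) {
    tr <- truth
    if (severity_slope != 0 && i <= n_pd)
      tr$roi_amplitudes["doorway", "PFC"] <-
        tr$roi_amplitudes["doorway", "PFC"] + severity_slope * zsev[i]
    generateSession(spec, tr, metas[[i]], seed = .childSeed(seed, i))
  })
}
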