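#' Pipeline configuration
#'
#' All stage parameters with the study's printed defaults, plus the
#' cohort/simulation sizes and the ablation switches that reproduce the
#' confound-correction demonstration (skipping the short-channel block,
#' the movement block, or both).
#'
#' @param seed Master seed for generation and model fitting.
#' @param n_pd,n_hc Synthetic cohort sizes.
#' @param protocol A [protocolSpec()].
#' @param truth A [groundTruth()].
#' @param target_fs Analysis rate (60 Hz, the movement-data clock).
#' @param sqi_window_s Signal-quality scoring window (10 s).
#' @param prune Apply signal-quality channel pruning (disable for
#'   noise-free simulations, which carry no cardiac band to score).
#' @param spline Named list: `stdv_threshold` 65, `amplitude_threshold`
#'   0.05, `t_motion` 0.5, `t_mask` 1.
#' @param wavelet_iqr Wavelet fence multiplier (0.8).
#' @param pre_lowpass Named list `fc` 0.5 Hz, `order` 3.
#' @param k_components Short-channel PCA components (8).
#' @param use_short_channels,use_motion Ablation switches for the
#'   confound regression blocks.
#' @param band Named list `hp_hz` 0.01, `hp_order` 2, `lp_hz` 0.1,
#'   `lp_order` 6.
#' @param merge_tolerance_s Rater-merge tolerance (2 s).
#' @param exclusion_s Freeze/successful-event exclusion window (10 s).
#' @param v_stop,omega_turn Kinematic thresholds (0.1 m/s, 30 deg/s).
#' @param windows Named list `early` `c(0, 3)`, `late` `c(7, 10)`,
#'   `baseline` `c(-10, -5)` seconds.
#' @param fit_models Fit the hierarchical models in [runPipeline()].
#' @param mcmc A [modelSpec()]-like list of MCMC sizes.
#' @param strict Turn warnings into errors.
#' @return List of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(seed = 1, n_pd = 4, n_hc = 4,
                           protocol = protocolSpec(),
                           truth = groundTruth(),
                           target_fs = 60, sqi_window_s = 10,
                           prune = TRUE,
                           spline = list(stdv_threshold = 65,
                                         amplitude_threshold = 0.05,
                                         t_motion = 0.5, t_mask = 1),
                           wavelet_iqr = 0.8,
                           pre_lowpass = list(fc = 0.5, order = 3),
                           k_components = 8,
                           use_short_channels = TRUE, use_motion = TRUE,
                           band = list(hp_hz = 0.01, hp_order = 2,
                                       lp_hz = 0.1, lp_order = 6),
                           merge_tolerance_s = 2, exclusion_s = 10,
                           v_stop = 0.1, omega_turn = 30,
                           windows = list(early = c(0, 3),
                                          late = c(7, 10),
                                          baseline = c(-10, -5)),
                           fit_models = TRUE,
                           mcmc = list(chains = 2, draws = 1000,
                                       warmup = 600),
                           strict = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Process one session through the full pre-processing chain
#'
#' Resampling to the movement clock, signal-quality pruning, optical
#' density, spline + wavelet direct-artifact correction, MBLL conversion,
#' 0.5 Hz low-pass, short-channel-PCA + head-kinematics confound
#' regression (per run, on the unstandardized concentration signal),
#' band filtering, per-run z-transform, annotation merging, event
#' selection, and event-locked ROI epoching.
#'
#' @param session A `"fog_session"` (or a compatible list with `runs`,
#'   `montage`, `raterA`, `raterB`, `events`, `meta`).
#' @param config A [pipelineConfig()].
#' @return List: `epochs_roi`, `epochs_channel` (long-format tables with
#'   participant metadata attached), `truth_epochs` (if the session
#'   carries ground truth), `consensus`, `selected`, `pct_time_frozen`,
#'   `sqi`, `regression` (per-run reports), `dropped_events`.
#' @export
processSession <- function(session, config = pipelineConfig()) {
  montage <- session$montage
  meta <- session$meta
  merged <- mergeAnnotations(session$raterA, session$raterB,
                             config$merge_tolerance_s)
  consensus <- merged$consensus
  roiT <- list(); chT <- list(); truthT <- list()
  sqiReps <- list(); regReps <- list(); dropped <- 0L
  selectedAll <- list(); scaleSd <- list()
  for (r in names(session$runs)) {
    rec <- session$runs[[r]]$recording
    kin <- session$runs[[r]]$kinematics
    evProt <- session$events[session$events$run == r, , drop = FALSE]

    rec <- resampleRecording(rec, config$target_fs)
    if (config$prune) {
      standing <- evProt[evProt$type == "stand", , drop = FALSE]
      sqi <- computeSqi(rec, standing, config$sqi_window_s)
      rec <- pruneChannels(rec, sqi)
      sqiReps[[r]] <- sqi
    }
    od <- intensityToOd(rec)
    od <- correctSpline(od, config$spline$stdv_threshold,
                        config$spline$amplitude_threshold,
                        config$spline$t_motion, config$spline$t_mask)
    od <- correctWavelet(od, config$wavelet_iqr)
    hb <- odToHb(od, montage, age_years = meta$age)
    cls <- splitByClass(hb, montage)
    nmin <- min(nSamples(cls$long), nSamples(kin))
    long <- cls$long; long@data <- long@data[, seq_len(nmin), drop = FALSE]
    short <- cls$short
    short@data <- short@data[, seq_len(nmin), drop = FALSE]
    kin@data <- kin@data[seq_len(nmin), , drop = FALSE]

    longF <- lowpassFilter(long, config$pre_lowpass$fc,
                           config$pre_lowpass$order)
    regs <- NULL
    if (config$use_short_channels) {
      shortF <- lowpassFilter(short, config$pre_lowpass$fc,
                              config$pre_lowpass$order)
      pcs <- pcaShortChannels(shortF, config$k_components)
      regs <- pcs$scores
    }
    if (config$use_motion) {
      kinF <- lowpassFilter(kin, config$pre_lowpass$fc,
                            config$pre_lowpass$order)
      mot <- buildMotionRegressors(kinF)
      regs <- if (is.null(regs)) mot else cbind(regs, mot)
    }
    if (!is.null(regs) && ncol(regs) > 0) {
      rr <- regressConfounds(longF, regs)
      longF <- rr$residuals
      regReps[[r]] <- rr$report
    }
    longF <- bandFilter(longF, config$band$hp_hz, config$band$hp_order,
                        config$band$lp_hz, config$band$lp_order)
    z <- zscorePerRun(longF)
    scaleSd[[r]] <- attr(z, "scale_sd")

    ## events for this run: consensus freezes + detected gait events
    consR <- consensus[consensus$run == r, , drop = FALSE]
    geom <- list(door_x = (max(kin@data[, "pos_x"]) +
                             min(kin@data[, "pos_x"])) / 2)
    det <- detectGaitEvents(kin, geom, config$v_stop,
                            min_halt_s = 2, config$omega_turn)
    det$run <- r
    sel <- selectEvents(consR, det, config$exclusion_s)
    selectedAll[[r]] <- sel
    sel <- poolTurns(sel)

    epoE <- epochEvents(z, sel, config$windows$early,
                        config$windows$baseline, "early")
    late <- sel[sel$type %in% c("stop", "start"), , drop = FALSE]
    epoL <- epochEvents(z, late, config$windows$late,
                        config$windows$baseline, "late")
    dropped <- dropped + attr(epoE, "dropped") + attr(epoL, "dropped")
    cht <- rbind(epoE, epoL)
    if (nrow(cht)) {
      cht <- cht[cht$chromophore == "HbO", , drop = FALSE]
      chT[[r]] <- cht
      roiT[[r]] <- roiAverage(cht, montage)
    }
    if (!is.null(session$truth$neural_z)) {
      # truth reference passes through the same band filter but keeps
      # the generator's amplitude units; recovery comparisons undo the
      # per-run z-scale on the estimates (see scaleSd) so both are in
      # concentration-equivalent units
      tr <- truthRecording(session, r)
      tr@data <- tr@data[, seq_len(nmin), drop = FALSE]
      tr <- bandFilter(tr, config$band$hp_hz, config$band$hp_order,
                       config$band$lp_hz, config$band$lp_order)
      te <- rbind(epochEvents(tr, sel, config$windows$early,
                              config$windows$baseline, "early"),
                  epochEvents(tr, late, config$windows$late,
                              config$windows$baseline, "late"))
      if (nrow(te)) {
        te$roi <- te$channel
        truthT[[r]] <- te
      }
    }
  }
  addMeta <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return(tbl)
    tbl$participant <- meta$id
    tbl$group <- meta$group
    tbl$updrs <- meta$updrs
    tbl
  }
  taskDur <- sum(vapply(session$runs, function(rr)
    nSamples(rr$kinematics) / samplingRate(rr$kinematics), 0))
  pct <- percentTimeFrozen(consensus, taskDur)
  roi <- addMeta(if (length(roiT)) do.call(rbind, roiT) else NULL)
  if (!is.null(roi) && nrow(roi)) roi$pct_time_frozen <- pct
  list(epochs_roi = roi,
       epochs_channel = addMeta(if (length(chT)) do.call(rbind, chT)
                                else NULL),
       truth_epochs = if (length(truthT)) do.call(rbind, truthT) else NULL,
       consensus = consensus, disputed = merged$disputed,
       selected = if (length(selectedAll)) do.call(rbind, selectedAll)
                  else eventTable(),
       pct_time_frozen = pct, sqi = sqiReps, regression = regReps,
       scale_sd = scaleSd, dropped_events = dropped)
}

#' Compare pipeline epoch estimates against the generator's ground truth
#'
#' Rescales the channel-level epoch values from per-run z-units back to
#' concentration-equivalent amplitude units (multiplying by the recorded
#' per-channel standard deviations and dividing by the generator's
#' micromolar-per-amplitude calibration), averages them per ROI, and
#' joins them with the ground-truth epochs, so estimate and truth share
#' one unit regardless of which confound blocks were regressed.
#'
#' @param res A [processSession()] result from a session with ground
#'   truth.
#' @param session The `"fog_session"` the result came from.
#' @return Data frame with columns `run`, `event_id`, `condition`,
#'   `trigger`, `roi`, `window`, `estimate`, `truth`.
#' @export
recoveryComparison <- function(res, session) {
  ch <- res$epochs_channel
  if (is.null(ch) || !nrow(ch)) return(NULL)
  hbz <- session$truth$spec$hb_per_z
  sds <- unlist(lapply(names(res$scale_sd), function(r)
    stats::setNames(res$scale_sd[[r]],
                    paste(r, names(res$scale_sd[[r]])))))
  key <- paste(ch$run, ch$row_id)
  ch$amp <- ch$value * unname(sds[key]) / hbz
  rmap <- roiOf(session$montage)
  ch$roi <- rmap[ch$channel]
  ch <- ch[!is.na(ch$roi) & ch$roi != "none", , drop = FALSE]
  est <- stats::aggregate(amp ~ run + event_id + condition + trigger +
                            window + roi, data = ch, FUN = mean)
  tru <- res$truth_epochs
  tru$roi <- tru$channel
  out <- merge(est, tru[, c("run", "event_id", "window", "roi", "value")],
               by = c("run", "event_id", "window", "roi"))
  names(out)[names(out) == "amp"] <- "estimate"
  names(out)[names(out) == "value"] <- "truth"
  out
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Generates each participant's session from the config seed, processes
#' it through [processSession()] (participants are streamed, not held in
#' memory), pools the epoch tables, fits the group model per condition
#' and ROI (early window), and writes the outputs: `epochs_roi.tsv`,
#' `epochs_channel.tsv`, `posteriors.tsv`, `events_consensus.tsv`, a
#' provenance `manifest.json` (config hash, versions, per-stage counts)
#' and `pipeline.log`. Deterministic given the seed.
#'
#' @param config A [pipelineConfig()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the pooled tables, fitted summaries and
#'   the manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  if (config$strict) {
    op <- options(warn = 2); on.exit(options(op), add = TRUE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  logline("pipeline start; seed=", config$seed)
  metasDrawn <- .withSeed(.childSeed(config$seed, 99L), {
    sev <- pmax(0.2, stats::rnorm(config$n_pd, 1, 0.35))
    lapply(seq_len(config$n_pd + config$n_hc), function(i) {
      pd <- i <= config$n_pd
      participantMeta(
        id = sprintf("sub-%02d", i), group = if (pd) "PD" else "HC",
        age = round(stats::rnorm(1, 66, 9)),
        fog_severity = if (pd) sev[i] else 0,
        updrs = if (pd) round(stats::rnorm(1, 43.7, 10.5)) else 0,
        cruise_speed = stats::rnorm(1, if (pd) 0.95 else 1.09, 0.07))
    })
  })
  roiAll <- list(); chAll <- list(); consAll <- list()
  counts <- list()
  for (i in seq_along(metasDrawn)) {
    meta <- metasDrawn[[i]]
    stage <- function(what, expr)
      tryCatch(expr, error = function(e)
        stop("stage [", what, "] failed for ", meta$id, ": ",
             conditionMessage(e), call. = FALSE))
    sess <- stage("synth",
                  generateSession(config$protocol, config$truth, meta,
                                  seed = .childSeed(config$seed, i)))
    res <- stage("process", processSession(sess, config))
    roiAll[[i]] <- res$epochs_roi
    chAll[[i]] <- res$epochs_channel
    cc <- res$consensus
    if (nrow(cc)) { cc$participant <- meta$id; consAll[[i]] <- cc }
    counts[[meta$id]] <- c(
      freezes = sum(sess$events$type == "freeze"),
      consensus = nrow(res$consensus), selected = nrow(res$selected),
      epoch_rows = if (is.null(res$epochs_roi)) 0L
                   else nrow(res$epochs_roi),
      dropped = res$dropped_events)
    logline(meta$id, " processed: ",
            paste(names(counts[[meta$id]]), counts[[meta$id]],
                  sep = "=", collapse = " "))
  }
  roi <- do.call(rbind, roiAll[!vapply(roiAll, is.null, TRUE)])
  chans <- do.call(rbind, chAll[!vapply(chAll, is.null, TRUE)])
  post <- NULL
  if (config$fit_models && !is.null(roi) && nrow(roi)) {
    post <- list()
    for (cond in intersect(c("stop", "turn", "doorway", "start"),
                           unique(roi$condition))) {
      for (roiName in unique(roi$roi)) {
        sub <- roi[roi$condition == cond & roi$roi == roiName &
                     roi$window == "early", , drop = FALSE]
        if (length(unique(sub$participant)) < 2) next
        sp <- modelSpec("group", chains = config$mcmc$chains,
                        draws = config$mcmc$draws,
                        warmup = config$mcmc$warmup,
                        seed = .childSeed(config$seed, 500 +
                                            length(post)))
        fit <- fitHierModel(sub, sp)
        s <- fit$summary[fit$summary$effect %in%
                           c("intercept", "group"), , drop = FALSE]
        s$condition <- cond; s$roi <- roiName
        post[[length(post) + 1L]] <- s
      }
    }
    post <- if (length(post)) do.call(rbind, post) else NULL
    logline("models fitted: ", if (is.null(post)) 0 else nrow(post) / 2)
  }
  utils::write.table(roi, file.path(outdir, "epochs_roi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(chans, file.path(outdir, "epochs_channel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(post))
    utils::write.table(post, file.path(outdir, "posteriors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- do.call(rbind, consAll[!vapply(consAll, is.null, TRUE)])
  if (!is.null(cons) && nrow(cons))
    utils::write.table(cons, file.path(outdir, "events_consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config_hash = .configHash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gaitfnirs")),
    r_version = R.version.string,
    ablation = list(short_channels = config$use_short_channels,
                    motion = config$use_motion),
    participants = names(counts),
    counts = counts,
    epoch_rows = if (is.null(roi)) 0L else nrow(roi))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("pipeline done")
  invisible(list(epochs_roi = roi, epochs_channel = chans,
                 posteriors = post, manifest = manifest, outdir = outdir))
}

# order-stable FNV-1a hash of the serialized config
.configHash <- function(config) {
  s <- jsonlite::serializeJSON(config)
  bytes <- utf8ToInt(as.character(s))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(h, b) * 31 + 7) %% 2^31
  sprintf("%08x", h)
}
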