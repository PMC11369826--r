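# independent enumeration of the deterministic task schedule: arrivals at
# walking-leg spacing, a stop every `every`-th arrival (mid-stop turn in the
# square, post-stop door crossing at the door), turn/door arrivals
# alternating
enumScheduleCounts <- function(run_len = 390, stand = 60, leg = 20,
                               stopdur = 30, every = 5) {
  t <- stand
  counts <- c(stand = 1, start = 1, stop = 0, doorway = 0, turn = 0)
  arrival <- "door"; k <- 0
  repeat {
    t <- t + leg
    if (t > run_len - 1) break
    k <- k + 1
    if (k %% every == 0 && t + stopdur <= run_len) {
      counts["stop"] <- counts["stop"] + 1
      if (arrival == "end") counts["turn"] <- counts["turn"] + 1
      t <- t + stopdur
      counts["start"] <- counts["start"] + 1
      if (arrival == "door") counts["doorway"] <- counts["doorway"] + 1
    } else if (arrival == "door") {
      counts["doorway"] <- counts["doorway"] + 1
    } else {
      counts["turn"] <- counts["turn"] + 1
    }
    arrival <- if (arrival == "door") "end" else "door"
  }
  counts
}

test_that("protocol schedule matches independent enumeration", {
  ev <- generateProtocol(protocolSpec(), seed = 1, fog_severity = 0)
  expected <- enumScheduleCounts()
  for (r in unique(ev$run)) {
    er <- ev[ev$run == r, ]
    expect_equal(sum(er$type == "stand"), unname(expected["stand"]))
    expect_equal(sum(er$type == "start"), unname(expected["start"]))
    expect_equal(sum(er$type == "stop"), unname(expected["stop"]))
    expect_equal(sum(er$type == "doorway"), unname(expected["doorway"]))
    expect_equal(sum(er$type %in% c("turn_left", "turn_right")),
                 unname(expected["turn"]))
  }
})

test_that("protocol freezes obey rates and determinism", {
  # zero freeze rate -> no freeze rows
  ev0 <- generateProtocol(protocolSpec(), seed = 2, fog_severity = 0)
  expect_false(any(ev0$type == "freeze"))
  # same seed -> identical tables; different seed -> different freezes
  a <- generateProtocol(protocolSpec(), seed = 3)
  b <- generateProtocol(protocolSpec(), seed = 3)
  d <- generateProtocol(protocolSpec(), seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$onset[a$type == "freeze"],
                         d$onset[d$type == "freeze"]))
  # every freeze carries a trigger
  expect_true(all(a$trigger[a$type == "freeze"] != "none"))
  # turn directions alternate within walking sequences
  tw <- a[a$type %in% c("turn_left", "turn_right") & a$run == "run-01", ]
  expect_gt(nrow(tw), 2)
})

test_that("session generation is reproducible and respects toggles", {
  sp <- protocolSpec(n_runs = 1, run_length_s = 200)
  s1 <- generateSession(sp, seed = 5)
  s2 <- generateSession(sp, seed = 5)
  expect_identical(s1$runs[["run-01"]]$recording@data,
                   s2$runs[["run-01"]]$recording@data)
  expect_identical(channelData(s1$runs[["run-01"]]$kinematics),
                   channelData(s2$runs[["run-01"]]$kinematics))
  # all signal sources disabled -> constant intensities
  amps0 <- 0 * groundTruth()$roi_amplitudes
  tr0 <- groundTruth(roi_amplitudes = amps0, systemic_amps_uM = 0,
                     coupling_mean_uM_deg = 0, coupling_sd_uM_deg = 0,
                     freeze_surge_uM = 0, noise_od_sd = 0,
                     p_spike = 0, p_shift = 0)
  s0 <- generateSession(sp, truth = tr0,
                        meta = participantMeta(group = "HC"), seed = 6)
  dat <- s0$runs[["run-01"]]$recording@data
  expect_lt(max(apply(dat, 1, function(x) diff(range(x)))), 1e-12)
  # non-finite amplitudes rejected
  ampsBad <- amps0; ampsBad[1, 1] <- NaN
  expect_error(generateSession(sp, truth = groundTruth(
    roi_amplitudes = ampsBad), seed = 1), "finite")
})

test_that("systemic-only sessions correlate long and short channels as the
           loading design predicts", {
  amps0 <- 0 * groundTruth()$roi_amplitudes
  tr <- groundTruth(roi_amplitudes = amps0, coupling_mean_uM_deg = 0,
                    coupling_sd_uM_deg = 0, freeze_surge_uM = 0,
                    noise_od_sd = 0, p_spike = 0, p_shift = 0)
  s <- generateSession(protocolSpec(n_runs = 1), truth = tr, seed = 11)
  od <- intensityToOd(s$runs[["run-01"]]$recording)
  L <- s$truth$loadings
  ch <- montageChannels(s$montage)
  lo <- ch$id[ch$kind == "long"][1:6]
  sh <- ch$id[ch$kind == "short"][1:6]
  emp <- pred <- c()
  for (a in lo) for (b in sh) {
    ra <- which(od@channel == a & od@wavelength == 760)
    rb <- which(od@channel == b & od@wavelength == 760)
    emp <- c(emp, cor(od@data[ra, ], od@data[rb, ]))
    pred <- c(pred, sum(L[a, ] * L[b, ]) /
                sqrt(sum(L[a, ]^2) * sum(L[b, ]^2)))
  }
  expect_lt(mean(abs(emp - pred)), 0.05)
  expect_gt(median(emp), 0.9)
})

test_that("short channels carry no neural component", {
  # neural + noise only: the event design explains the long channels but
  # not the short ones
  tr <- groundTruth(systemic_amps_uM = 0, coupling_mean_uM_deg = 0,
                    coupling_sd_uM_deg = 0, freeze_surge_uM = 0,
                    p_spike = 0, p_shift = 0)
  s <- generateSession(protocolSpec(n_runs = 1), truth = tr, seed = 12)
  ev <- s$events[s$events$run == "run-01", ]
  od <- intensityToOd(s$runs[["run-01"]]$recording)
  hb <- lowpassFilter(odToHb(od, s$montage, age_years = s$meta$age))
  n <- nSamples(hb)
  amps <- diag(5)
  dimnames(amps) <- list(c("stop", "start", "turn", "doorway", "freeze"),
                         c("M1", "PMC", "SMA", "PFC", "PPC"))
  design <- t(neuralTimecourses(ev, amps, samplingRate(hb), n))
  r2 <- function(rows) {
    mean(vapply(rows, function(r) {
      f <- stats::lm.fit(cbind(1, design), hb@data[r, ])
      1 - sum(f$residuals^2) / sum((hb@data[r, ] -
                                      mean(hb@data[r, ]))^2)
    }, 0))
  }
  ch <- montageChannels(s$montage)
  shortRows <- which(hb@channel %in% ch$id[ch$kind == "short"] &
                       hb@chromophore == "HbO")
  longRows <- which(hb@channel %in% ch$id[ch$kind == "long"] &
                      hb@chromophore == "HbO")
  expect_lt(r2(shortRows), 0.05)
  expect_gt(r2(longRows), 0.6)
})

test_that("rater B is rater A jittered within the merge tolerance", {
  s <- sharedSession()
  expect_gt(nrow(s$raterA), 0)
  expect_equal(nrow(s$raterA), nrow(s$raterB))
  gap <- abs(s$raterA$onset - s$raterB$onset)
  expect_true(all(gap <= 2))
  expect_true(all(s$raterA$type == "freeze"))
})

test_that("cohort generation draws group-consistent metadata", {
  co <- generateCohort(1, 1, protocolSpec(n_runs = 1, run_length_s = 200),
                       seed = 77)
  expect_length(co, 2L)
  expect_equal(co[[1]]$meta$group, "PD")
  expect_equal(co[[2]]$meta$group, "HC")
  expect_gt(co[[1]]$meta$fog_severity, 0)
  expect_equal(co[[2]]$meta$fog_severity, 0)
  expect_false(any(co[[2]]$events$type == "freeze"))
})
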