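test_that("resampling preserves sinusoid amplitude and duration", {
  fs <- 50
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  dat <- rbind(`S1-D1@760` = x, `S1-D1@850` = x)
  rec <- fnirsRecording(dat, fs = fs, unit = "raw_intensity",
                        wavelength = c(760, 850))
  out <- resampleRecording(rec, 60)
  expect_equal(samplingRate(out), 60)
  # duration preserved within one sample
  expect_lt(abs(nSamples(out) / 60 - nSamples(rec) / 50), 1 / 50)
  mid <- 300:3200
  expect_lt(abs(max(abs(out@data[1, mid])) - 1), 0.01)
  # identity when target equals current rate
  expect_identical(resampleRecording(rec, 50), rec)
  # constant stays constant
  cst <- fnirsRecording(matrix(2, 1, 500,
                               dimnames = list("S1-D1@760", NULL)),
                        fs = 50, unit = "raw_intensity", wavelength = 760)
  expect_lt(max(abs(resampleRecording(cst, 60)@data[1, ] - 2)), 1e-6)
})

test_that("signal-quality pruning follows the standing-window rule", {
  set.seed(7)
  fs <- 50; n <- 60 * fs
  tt <- (seq_len(n) - 1) / fs
  # channel with a cardiac oscillation survives; pure white noise does not
  cardiac <- 1 + 0.004 * sin(2 * pi * 1.2 * tt) + rnorm(n, 0, 0.0015)
  noise <- 1 + rnorm(n, 0, 0.0015)
  dat <- rbind(`S1-D1@760` = cardiac, `S2-D2@760` = noise)
  rec <- fnirsRecording(dat, fs = fs, unit = "raw_intensity",
                        wavelength = c(760, 760),
                        channel = c("S1-D1", "S2-D2"))
  standing <- eventTable(onset = 0, duration = 60, type = "stand")
  rep <- computeSqi(rec, standing)
  expect_true(all(rep$fraction_below2 >= 0) &&
                all(rep$fraction_below2 <= 1))
  expect_false(rep$pruned[rep$channel == "S1-D1"])
  expect_true(rep$pruned[rep$channel == "S2-D2"])
  pruned <- pruneChannels(rec, rep)
  expect_equal(unname(channelMask(pruned)), c(FALSE, TRUE))
  # data untouched by pruning
  expect_identical(pruned@data, rec@data)
  # all channels clean -> empty prune set
  dat2 <- rbind(`S1-D1@760` = cardiac, `S2-D2@760` = cardiac)
  rec2 <- fnirsRecording(dat2, fs = fs, unit = "raw_intensity",
                         wavelength = c(760, 760))
  expect_equal(sum(computeSqi(rec2, standing)$pruned), 0L)
  # missing standing intervals -> explicit error
  expect_error(computeSqi(rec, eventTable()), "standing")
})

test_that("optical density conversion matches its definition", {
  # constant intensity -> all-zero OD
  cst <- fnirsRecording(matrix(3, 1, 100,
                               dimnames = list("S1-D1@760", NULL)),
                        fs = 50, unit = "raw_intensity", wavelength = 760)
  expect_equal(max(abs(intensityToOd(cst)@data)), 0)
  # I = mean * 10^(-x) -> OD = x (up to the mean-reference offset)
  x <- c(0.1, -0.1, 0.05, -0.05)
  I0 <- 10^(-x); I0 <- I0 / mean(I0)   # force mean exactly 1
  rec <- fnirsRecording(matrix(I0, 1, 4,
                               dimnames = list("S1-D1@760", NULL)),
                        fs = 50, unit = "raw_intensity", wavelength = 760)
  od <- intensityToOd(rec)
  expect_equal(od@data[1, ], -log10(I0), tolerance = 1e-12)
  # round trip od -> intensity -> od recovers shape up to a constant
  set.seed(1)
  odv <- cumsum(rnorm(200, 0, 0.01))
  I <- 1.7 * 10^(-odv)
  rec2 <- fnirsRecording(matrix(I, 1, 200,
                                dimnames = list("S1-D1@760", NULL)),
                         fs = 50, unit = "raw_intensity", wavelength = 760)
  diffv <- intensityToOd(rec2)@data[1, ] - odv
  expect_lt(diff(range(diffv)), 1e-12)
  # non-positive samples are rejected with the channel named
  recBad <- fnirsRecording(matrix(c(1, -0.1, 1, 1), 1, 4,
                                  dimnames = list("S1-D1@760", NULL)),
                           fs = 50, unit = "raw_intensity",
                           wavelength = 760)
  expect_error(intensityToOd(recBad), "S1-D1@760")
})

test_that("spline correction removes spikes and shifts, leaving clean data
           bit-identical", {
  set.seed(3)
  fs <- 60; n <- 120 * fs
  sigma <- 0.002
  clean <- rnorm(n, 0, sigma)
  # artifact-free segment -> identity
  od0 <- odRecording(clean, fs)
  expect_identical(correctSpline(od0)@data, od0@data)
  # spike of 10x the clean windowed amplitude at a known time
  x <- clean
  spikeIdx <- 3000:3030
  x[spikeIdx] <- x[spikeIdx] + 0.08 * sin(pi * seq_along(spikeIdx) / 31)
  od <- odRecording(x, fs)
  out <- correctSpline(od)
  fl <- attr(out, "motion_flags")[1, ]
  expect_true(all(fl[spikeIdx]))                    # flags cover the spike
  expect_lt(max(abs(out@data[1, spikeIdx])), 2 * sigma)
  expect_identical(out@data[1, !fl], od@data[1, !fl])  # unflagged unchanged
  # transient baseline shift reduced by >= 90%
  y <- clean
  shiftIdx <- 4000:4180                              # 3 s plateau
  y[shiftIdx] <- y[shiftIdx] + 0.1
  ods <- odRecording(y, fs)
  outs <- correctSpline(ods)
  stepBefore <- abs(mean(y[shiftIdx]) - mean(y[1:3900]))
  stepAfter <- abs(mean(outs@data[1, shiftIdx]) -
                     mean(outs@data[1, 1:3900]))
  expect_lt(stepAfter, 0.1 * stepBefore)
})

test_that("wavelet correction behaves as the fence rule predicts", {
  set.seed(4)
  fs <- 60; n <- 4096
  # Gaussian noise: ~92% of detail coefficients inside the 0.8*IQR fences
  # stay; variance drops by the clipped-tail share (analytically ~0.63 of
  # total, approximation band included)
  x <- rnorm(n)
  od <- odRecording(x, fs)
  out <- correctWavelet(od)
  expect_equal(length(out@data[1, ]), n)
  ratio <- var(out@data[1, ]) / var(x)
  expect_gt(ratio, 0.5)
  expect_lt(abs(ratio - 0.63), 0.1)
  # single large short spike attenuated by >= 80%
  y <- rnorm(n, 0, 0.002)
  idx <- 2000:2024                                    # ~0.4 s
  y[idx] <- y[idx] + 0.5 * sin(pi * seq_along(idx) / 26)
  ody <- odRecording(y, fs)
  outy <- correctWavelet(ody)
  expect_lt(max(outy@data[1, idx]), 0.2 * 0.5)
  # all-zero signal stays all-zero
  odz <- odRecording(rep(0, n), fs)
  expect_equal(max(abs(correctWavelet(odz)@data)), 0)
})

test_that("MBLL solves and round-trips the two-wavelength system", {
  m <- tinyMontage()
  n <- 50
  ids <- montageChannels(m)$id
  # forward from known concentrations, then invert: recovery to 1e-10
  hbo <- rep(1.0, n); hbr <- rep(-0.3, n)
  dat <- matrix(rep(rbind(hbo, hbr), length(ids)) , 2 * length(ids), n,
                byrow = FALSE)
  dat <- do.call(rbind, lapply(ids, function(i) rbind(hbo, hbr)))
  rownames(dat) <- as.vector(rbind(paste0(ids, "@HbO"),
                                   paste0(ids, "@HbR")))
  hb <- fnirsRecording(dat, fs = 50, unit = "micromolar",
                       channel = rep(ids, each = 2),
                       chromophore = rep(c("HbO", "HbR"), length(ids)))
  od <- hbToOd(hb, m, age_years = 66)
  back <- odToHb(od, m, age_years = 66)
  expect_lt(max(abs(back@data - hb@data)), 1e-10)
  # zero OD -> zero concentrations
  od0 <- od; od0@data[] <- 0
  expect_equal(max(abs(odToHb(od0, m, age_years = 66)@data)), 0)
  # linearity: mbll(a x + b y) = a mbll(x) + b mbll(y)
  set.seed(2)
  odA <- od; odA@data <- matrix(rnorm(length(od@data), 0, 0.01),
                                nrow(od@data))
  odB <- od; odB@data <- matrix(rnorm(length(od@data), 0, 0.01),
                                nrow(od@data))
  odMix <- od; odMix@data <- 2 * odA@data - 3 * odB@data
  lhs <- odToHb(odMix, m, age_years = 66)@data
  rhs <- 2 * odToHb(odA, m, age_years = 66)@data -
    3 * odToHb(odB, m, age_years = 66)@data
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # singular extinction matrix is rejected
  epsBad <- rbind(HbO = c(1, 1), HbR = c(1, 1))
  colnames(epsBad) <- c("760", "850")
  expect_error(mbllCoefficients(m, 66, extinction = epsBad), "singular")
})

test_that("DPF follows the published general equation", {
  # spot values of the wavelength/age polynomial
  expect_equal(dpf(760, 30), 223.3 + 0.05624 * 30^0.8493 -
                 5.723e-7 * 760^3 + 0.001245 * 760^2 - 0.9025 * 760)
  expect_gt(dpf(760, 66), dpf(760, 30))   # DPF grows with age
  eps <- extinctionCoefficients(c(760, 850))
  # HbR absorbs more at 760, HbO more at 850 (the standard crossover)
  expect_gt(eps["HbR", "760"], eps["HbO", "760"])
  expect_gt(eps["HbO", "850"], eps["HbR", "850"])
})
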