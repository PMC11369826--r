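#' Resample a recording to a new rate
#'
#' Rational-ratio polyphase resampling (anti-alias filtered), used to bring
#' the 50 Hz optical data onto the 60 Hz movement-data clock. Duration is
#' preserved within one sample; a constant signal stays constant.
#'
#' @param recording A [FnirsRecording-class] in `raw_intensity` or
#'   `optical_density` units.
#' @param target_fs Target rate in Hz (60).
#' @return The resampled [FnirsRecording-class].
#' @export
resampleRecording <- function(recording, target_fs = 60) {
  stopifnot(signalUnit(recording) %in% c("raw_intensity", "optical_density"))
  if (isTRUE(all.equal(recording@fs, target_fs))) return(recording)
  fr <- .ratioFraction(target_fs / recording@fs)
  p <- fr[1]; q <- fr[2]
  n <- ncol(recording@data)
  nout <- floor(n * p / q)
  pad <- min(n - 1L, max(8L, round(recording@fs)))  # mirror-pad the edges
  out <- matrix(0, nrow(recording@data), nout,
                dimnames = list(rownames(recording@data), NULL))
  off <- round(pad * p / q)
  for (i in seq_len(nrow(recording@data))) {
    x <- recording@data[i, ]
    mu <- mean(x)                  # resample around the mean: the FIR
    x <- x - mu                    # polyphase ripple never touches DC
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
    y <- signal::resample(xp, p, q)
    out[i, ] <- y[off + seq_len(nout)] + mu
  }
  recording@data <- out
  recording@fs <- target_fs
  validObject(recording)
  recording
}

# small-rational approximation of a resampling ratio
.ratioFraction <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", r, " as a small rational")
}

#' Signal-quality scoring and channel pruning
#'
#' `computeSqi()` scores each channel on a 1-4 scale over the standing
#' intervals, window by window; `pruneChannels()` turns the report into a
#' channel mask. The decision rule follows the study design: a channel is
#' pruned iff its SQI is below 2 for more than half of the time the
#' participant stood still. The default scorer rates each 10 s window by
#' the cardiac-band signal-to-noise ratio: mean periodogram power in the
#' cardiac band (0.8-2.4 Hz) over the high-frequency noise floor
#' (3 Hz-0.9*Nyquist), mapped as `1 + 1.5*log10(SNR)` and clamped to
#' [1, 4]. A pluggable `scorer(window, fs)` can replace it.
#'
#' @param recording A [FnirsRecording-class] (raw intensity or OD).
#' @param standing An event table whose `stand`/`stop` rows define the
#'   quiet-standing intervals; must be non-empty.
#' @param window_s Scoring window length (s).
#' @param scorer Optional function `(x, fs) -> numeric SQI in [1, 4]`.
#' @return `computeSqi()`: data.frame (`row_id`, `channel`, `mean_sqi`,
#'   `fraction_below2`, `pruned`); `pruneChannels()`: logical mask per
#'   data row.
#' @export
computeSqi <- function(recording, standing, window_s = 10, scorer = NULL) {
  st <- standing[standing$type %in% c("stand", "stop"), , drop = FALSE]
  if (nrow(st) == 0L)
    stop("no standing intervals supplied; SQI needs explicit stand/stop ",
         "events")
  if (is.null(scorer)) scorer <- .sqiCardiac
  fs <- recording@fs
  idx <- integer()
  for (i in seq_len(nrow(st))) {
    a <- 1L + floor((st$onset[i] - recording@time0) * fs)
    b <- min(ncol(recording@data),
             floor((st$onset[i] + st$duration[i] - recording@time0) * fs))
    if (b > a) idx <- c(idx, a:b)
  }
  idx <- idx[idx >= 1L]
  w <- max(16L, round(window_s * fs))
  starts <- seq(1L, length(idx) - w + 1L, by = w)
  if (!length(starts)) stop("standing intervals shorter than one SQI window")
  res <- lapply(seq_len(nrow(recording@data)), function(r) {
    sq <- vapply(starts, function(s0) {
      scorer(recording@data[r, idx[s0:(s0 + w - 1L)]], fs)
    }, 0)
    data.frame(row_id = rownames(recording@data)[r],
               channel = recording@channel[r],
               mean_sqi = mean(sq), fraction_below2 = mean(sq < 2),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, res)
  rep$pruned <- rep$fraction_below2 > 0.5
  rep
}

# default SQI scorer: cardiac-band SNR mapped to [1,4]
.sqiCardiac <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  p <- p[half]; f <- f[half]
  card <- p[f >= 0.8 & f <= 2.4]
  hi <- p[f >= 3 & f <= 0.9 * fs / 2]
  if (!length(card) || !length(hi) || mean(hi) == 0) return(1)
  snr <- mean(card) / mean(hi)
  min(4, max(1, 1 + 1.5 * log10(snr)))
}

#' @rdname computeSqi
#' @param report A report from `computeSqi()`.
#' @export
pruneChannels <- function(recording, report) {
  badch <- unique(report$channel[report$pruned])
  mask <- recording@channel %in% badch
  channelMask(recording) <- mask | recording@mask
  recording
}

#' Convert raw intensities to optical density changes
#'
#' `OD(t) = -log10(I(t) / mean(I))` per row, so each channel's OD is a
#' change measure with (approximately) zero mean.
#'
#' @param recording A [FnirsRecording-class] with `unit = "raw_intensity"`
#'   and strictly positive samples.
#' @return A [FnirsRecording-class] with `unit = "optical_density"`.
#' @export
intensityToOd <- function(recording) {
  stopifnot(signalUnit(recording) == "raw_intensity")
  bad <- which(apply(recording@data[!recording@mask, , drop = FALSE] <= 0,
                     1, any))
  if (length(bad))
    stop("non-positive intensity in channel ",
         rownames(recording@data)[!recording@mask][bad[1]])
  recording@data <- -log10(recording@data / rowMeans(recording@data))
  recording@unit <- "optical_density"
  recording
}

#' Spline correction of direct movement artifacts
#'
#' Detects motion-contaminated samples per channel -- windows of
#' `t_motion` seconds whose signal excursion exceeds either
#' `stdv_threshold` times the channel's difference-based noise scale or
#' the absolute `amplitude_threshold` -- extends each flagged region by
#' `t_mask` seconds, then replaces every flagged segment by the segment
#' minus a smoothing-spline fit of its artifact trajectory, re-levelled to
#' the mean of the adjoining clean data. Samples outside flagged segments
#' are returned bit-identical.
#'
#' @param od A [FnirsRecording-class] with `unit = "optical_density"`.
#' @param stdv_threshold Multiplier on the channel noise scale (65).
#' @param amplitude_threshold Absolute OD excursion threshold (0.05).
#' @param t_motion Detection window, seconds (0.5).
#' @param t_mask Flag extension, seconds (1).
#' @param spline_df_hz Smoothing-spline flexibility: spline degrees of
#'   freedom per second of artifact segment.
#' @return The corrected [FnirsRecording-class]; a `motion_flags`
#'   attribute carries the per-row flagged-sample matrix.
#' @export
correctSpline <- function(od, stdv_threshold = 65,
                          amplitude_threshold = 0.05, t_motion = 0.5,
                          t_mask = 1, spline_df_hz = 20) {
  stopifnot(signalUnit(od) == "optical_density")
  fs <- od@fs
  wlen <- max(2L, round(t_motion * fs))
  ext <- round(t_mask * fs)
  flags <- matrix(FALSE, nrow(od@data), ncol(od@data))
  n <- ncol(od@data)
  for (r in seq_len(nrow(od@data))) {
    if (od@mask[r]) next
    x <- od@data[r, ]
    sdev <- stats::sd(diff(x))
    # windowed excursion via running max/min
    runmax <- .runExtreme(x, wlen, max)
    runmin <- .runExtreme(x, wlen, min)
    exc <- runmax - runmin
    hit <- exc > (stdv_threshold * sdev) | exc > amplitude_threshold
    if (!any(hit)) next
    fl <- logical(n)
    hi <- which(hit)
    for (h in hi) fl[max(1L, h - ext):min(n, h + wlen - 1L + ext)] <- TRUE
    flags[r, ] <- fl
    od@data[r, ] <- .splineSegments(x, fl, fs, spline_df_hz)
  }
  attr(od, "motion_flags") <- flags
  od
}

# running windowed extreme over leading windows of length w
.runExtreme <- function(x, w, fun) {
  n <- length(x)
  pm <- if (identical(fun, max)) pmax else pmin
  out <- x[seq_len(n - w + 1L)]
  for (s in seq_len(w - 1L)) out <- pm(out, x[seq_len(n - w + 1L) + s])
  c(out, rep(out[length(out)], w - 1L))
}

# replace flagged segments by (segment - smoothing spline), re-levelled to
# the adjoining clean data; clean samples untouched
.splineSegments <- function(x, fl, fs, df_hz) {
  n <- length(x)
  r <- rle(fl)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (s in which(r$values)) {
    i0 <- starts[s]; i1 <- ends[s]
    seg <- x[i0:i1]
    m <- length(seg)
    df <- min(m - 1L, max(4L, round(df_hz * m / fs)))
    if (m >= 8L && df >= 4L) {
      fit <- stats::smooth.spline(seq_len(m), seg, df = df)
      resid <- seg - stats::predict(fit, seq_len(m))$y
    } else resid <- seg - mean(seg)
    # level: mean of the adjoining clean second (previous, else next)
    w <- max(1L, round(fs))
    level <- if (i0 > 1L) mean(x[max(1L, i0 - w):(i0 - 1L)])
             else if (i1 < n) mean(x[(i1 + 1L):min(n, i1 + w)])
             else mean(seg)
    x[i0:i1] <- resid + level
  }
  x
}

#' Wavelet correction of spike-like artifacts
#'
#' Per channel, a periodized Daubechies-2 discrete wavelet decomposition;
#' at every detail level, coefficients outside
#' `[Q1 - iqr*IQR, Q3 + iqr*IQR]` are treated as motion artifact and set
#' to zero; the signal is reconstructed at its original length. The
#' approximation band is untouched.
#'
#' @param od A [FnirsRecording-class] with `unit = "optical_density"`.
#' @param iqr Interquartile-range fence multiplier (0.8).
#' @param levels Decomposition depth; default decomposes to the deepest
#'   level retaining at least 32 approximation coefficients, so unipolar
#'   spike pulses (whose energy reaches down to near-DC) fall in the
#'   thresholded detail scales.
#' @return The corrected [FnirsRecording-class].
#' @export
correctWavelet <- function(od, iqr = 0.8, levels = NULL) {
  stopifnot(signalUnit(od) == "optical_density")
  n <- ncol(od@data)
  if (is.null(levels)) levels <- max(1L, floor(log2(n / 32)))
  for (r in seq_len(nrow(od@data))) {
    if (od@mask[r]) next
    pad <- .padPow2(od@data[r, ], levels)
    w <- .dwt(pad$x, levels)
    for (j in seq_along(w$details)) {
      d <- w$details[[j]]
      qs <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      fence <- c(qs[1] - iqr * (qs[2] - qs[1]),
                 qs[2] + iqr * (qs[2] - qs[1]))
      d[d < fence[1] | d > fence[2]] <- 0
      w$details[[j]] <- d
    }
    od@data[r, ] <- .idwt(w)[seq_len(pad$n)]
  }
  od
}
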