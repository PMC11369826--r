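#' Final band filtering
#'
#' Cascade of a 0.01 Hz second-order high-pass (slow drifts) and a 0.1 Hz
#' sixth-order low-pass (Mayer-wave band), both Butterworth and applied
#' zero-phase, retaining the task-related haemodynamic band.
#'
#' @param x A [FnirsRecording-class].
#' @param hp_hz,hp_order High-pass cut-off and order (0.01 Hz, 2).
#' @param lp_hz,lp_order Low-pass cut-off and order (0.1 Hz, 6).
#' @return The filtered [FnirsRecording-class]. Errors if the record is
#'   shorter than three high-pass periods (filter warm-up).
#' @export
bandFilter <- function(x, hp_hz = 0.01, hp_order = 2, lp_hz = 0.1,
                       lp_order = 6) {
  fs <- samplingRate(x)
  if (ncol(x@data) / fs < 3 / hp_hz)
    stop("record shorter than three high-pass periods (",
         round(3 / hp_hz), " s needed)")
  hp <- signal::butter(hp_order, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(lp_order, lp_hz / (fs / 2), type = "low")
  for (r in seq_len(nrow(x@data))) {
    if (x@mask[r]) next
    y <- .zfilt(hp, x@data[r, ])
    x@data[r, ] <- .zfilt(lp, y)
  }
  x
}

#' Per-run z-transform
#'
#' Standardizes every channel within the run (subtract the channel-run
#' mean, divide by its standard deviation), making channels of one ROI
#' averageable. Zero-variance channels are masked with a warning instead
#' of divided.
#'
#' @param x A [FnirsRecording-class].
#' @return The standardized recording, `unit = "zscore"`.
#' @export
zscorePerRun <- function(x) {
  sds <- rep(NA_real_, nrow(x@data))
  for (r in seq_len(nrow(x@data))) {
    if (x@mask[r]) next
    s <- stats::sd(x@data[r, ])
    if (!is.finite(s) || s == 0) {
      warning("zero-variance channel masked: ", rownames(x@data)[r])
      x@mask[r] <- TRUE
      next
    }
    sds[r] <- s
    x@data[r, ] <- (x@data[r, ] - mean(x@data[r, ])) / s
  }
  x@unit <- "zscore"
  attr(x, "scale_sd") <- stats::setNames(sds, rownames(x@data))
  x
}

#' Analytic Butterworth magnitude response
#'
#' Single-pass gain of the digitally designed filter at given frequencies
#' (bilinear transform, cut-off prewarped), for verifying the pipeline's
#' filters against the analytic `1/sqrt(1 + (f/fc)^(2n))` forms.
#'
#' @param fc Cut-off (Hz), `order` filter order, `fs` sampling rate,
#'   `type` `"low"`/`"high"`, `f` frequencies to evaluate (Hz).
#' @param order,fs,type,f See above.
#' @return Numeric gains at `f`.
#' @export
butterGain <- function(fc, order, fs, type = c("low", "high"), f) {
  type <- match.arg(type)
  bf <- signal::butter(order, fc / (fs / 2), type = type)
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz)
    sum(bf$b * zz^(-(seq_along(bf$b) - 1))), 0i)
  den <- vapply(z, function(zz)
    sum(bf$a * zz^(-(seq_along(bf$a) - 1))), 0i)
  Mod(num / den)
}
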