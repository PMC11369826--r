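#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used by the forward model and expected by the epoch
#' windows: a gamma density peaking ~6 s after the event minus a scaled
#' gamma undershoot peaking ~16 s, normalized to unit peak so that event
#' amplitudes are expressed on the response-peak scale.
#'
#' @param t Time grid in seconds (>= 0 contributes; negative times give 0).
#' @param peak_s Peak delay of the positive lobe (s).
#' @param undershoot_s Peak delay of the undershoot (s).
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @return Numeric vector, `h(t)`, peak value 1.
#' @examples
#' t <- seq(0, 30, by = 0.1)
#' h <- canonicalHrf(t)
#' t[which.max(h)]  # ~6 s
#' @export
canonicalHrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h[t < 0] <- 0
  tt <- seq(0, max(peak_s * 3, 20), by = 0.05)
  pk <- max(stats::dgamma(tt, shape = peak_s + 1, rate = 1) -
              ratio * stats::dgamma(tt, shape = undershoot_s + 1, rate = 1))
  h / pk
}

#' Event-related neural response time courses
#'
#' Boxcars over `[onset, onset + duration)` (durations clipped to
#' `boxcar_clip`) convolved with the canonical HRF, scaled by the
#' per-(condition, ROI) amplitude matrix. A pure function of the event
#' table, so ground truth can be materialized on any sampling grid
#' without touching the RNG; the kernel is normalized so a 5 s reference
#' event peaks at its nominal amplitude.
#'
#' @param events Event table.
#' @param amplitudes Conditions x ROI amplitude matrix.
#' @param fs Sampling rate (Hz).
#' @param n_samples Output length.
#' @param hrf_peak,hrf_undershoot,hrf_ratio Canonical HRF parameters.
#' @param boxcar_clip Length-2 clip bounds for event durations (s).
#' @return ROI x samples matrix.
#' @export
neuralTimecourses <- function(events, amplitudes, fs, n_samples,
                              hrf_peak = 6, hrf_undershoot = 16,
                              hrf_ratio = 1 / 6,
                              boxcar_clip = c(1, 10)) {
  rois <- colnames(amplitudes)
  out <- matrix(0, length(rois), n_samples,
                dimnames = list(rois, NULL))
  kern <- canonicalHrf(seq(0, 32, by = 1 / fs), hrf_peak, hrf_undershoot,
                       hrf_ratio)
  # normalize so a 5 s reference event peaks at its nominal amplitude,
  # making amplitudes sampling-rate independent
  ref <- stats::convolve(rep(1, round(5 * fs)), rev(kern),
                         type = "open")
  kern <- kern / max(ref)
  conds <- rownames(amplitudes)
  for (cond in conds) {
    ev <- events[.conditionOf(events) == cond, , drop = FALSE]
    if (nrow(ev) == 0L) next
    box <- numeric(n_samples)
    for (i in seq_len(nrow(ev))) {
      dur <- min(max(ev$duration[i], boxcar_clip[1]), boxcar_clip[2])
      i0 <- 1L + floor(ev$onset[i] * fs)
      i1 <- min(n_samples, floor((ev$onset[i] + dur) * fs))
      if (i0 <= n_samples && i1 >= i0) box[i0:i1] <- box[i0:i1] + 1
    }
    resp <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_samples)]
    for (roi in rois)
      out[roi, ] <- out[roi, ] + amplitudes[cond, roi] * resp
  }
  out
}

# condition label of each event row: freeze stays "freeze", turns pool
.conditionOf <- function(events) {
  ifelse(events$type %in% c("turn_left", "turn_right"), "turn", events$type)
}
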