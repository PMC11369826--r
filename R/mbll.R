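#' Extinction coefficients for HbO and HbR
#'
#' Molar extinction coefficients at the montage wavelengths, in
#' 1/(mM*cm), interpolated from the standard compiled absorption spectra
#' of oxy- and deoxyhaemoglobin shipped with the package
#' (`inst/extdata/hb_extinction.tsv`; see the provenance note there).
#'
#' @param wavelengths Numeric, wavelengths in nm.
#' @return 2 x length(wavelengths) matrix, rows `HbO`, `HbR`.
#' @examples
#' extinctionCoefficients(c(760, 850))
#' @export
extinctionCoefficients <- function(wavelengths = c(760, 850)) {
  path <- system.file("extdata", "hb_extinction.tsv", package = "gaitfnirs")
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  out <- rbind(
    HbO = stats::approx(tab$wavelength_nm, tab$hbo_1_mM_cm,
                        xout = wavelengths)$y,
    HbR = stats::approx(tab$wavelength_nm, tab$hbr_1_mM_cm,
                        xout = wavelengths)$y)
  colnames(out) <- as.character(wavelengths)
  if (anyNA(out)) stop("wavelength outside tabulated extinction range")
  out
}

#' Differential pathlength factor, wavelength- and age-dependent
#'
#' General polynomial DPF equation in age and wavelength
#' (fifth-order in wavelength terms, power law in age):
#' `DPF = a + b*A^c + d*l^3 + e*l^2 + f*l` with the published general
#' coefficients, valid for roughly 690-900 nm.
#'
#' @param wavelength_nm Wavelength in nm.
#' @param age_years Participant age in years.
#' @return DPF (dimensionless, > 0).
#' @examples
#' dpf(760, 66)  # ~6.4
#' @export
dpf <- function(wavelength_nm, age_years) {
  a <- 223.3; b <- 0.05624; cc <- 0.8493
  d <- -5.723e-7; e <- 0.001245; f <- -0.9025
  val <- a + b * age_years^cc + d * wavelength_nm^3 +
    e * wavelength_nm^2 + f * wavelength_nm
  if (any(val <= 0)) stop("DPF non-positive: wavelength out of valid range")
  val
}

#' MBLL coefficient bundle
#'
#' Builds the per-channel modified Beer-Lambert-law system: for each
#' channel, `dOD(lambda) = d_cm * DPF(lambda, age) *
#' (eps_HbO(lambda) * dHbO + eps_HbR(lambda) * dHbR)` with concentrations
#' in mM. The 2x2 extinction matrix must be invertible.
#'
#' @param montage A [FnirsMontage-class].
#' @param age_years Participant age (drives the DPF).
#' @param extinction Optional 2 x 2 override of [extinctionCoefficients()].
#' @return List with `eps` (2x2, rows HbO/HbR x wavelengths), `dpf`
#'   (length 2), `distance_cm` (named per channel id), `wavelengths`.
#' @export
mbllCoefficients <- function(montage, age_years,
                             extinction = NULL) {
  wl <- montage@wavelengths
  eps <- if (is.null(extinction)) extinctionCoefficients(wl) else extinction
  if (abs(det(t(eps))) < 1e-12)
    stop("singular extinction matrix: wavelengths do not separate HbO/HbR")
  ch <- montage@channels
  list(eps = eps, dpf = dpf(wl, age_years),
       distance_cm = stats::setNames(ch$distance_mm / 10, ch$id),
       wavelengths = wl)
}

#' Convert optical density to haemoglobin concentration changes
#'
#' Solves, per channel, the 2x2 modified Beer-Lambert system at the two
#' wavelengths for `dHbO` and `dHbR`, returning chromophore rows
#' (`"S#-D#@HbO"`, `"S#-D#@HbR"`) in micromolar. The map is linear, so
#' it commutes with any linear preprocessing applied to OD.
#'
#' @param od A [FnirsRecording-class] with `unit = "optical_density"` and
#'   two wavelength rows per channel.
#' @param montage The montage (for interoptode distances).
#' @param age_years Participant age in years (DPF).
#' @param coeffs Optional precomputed [mbllCoefficients()].
#' @return A [FnirsRecording-class], `unit = "micromolar"`, two chromophore
#'   rows per channel; the channel mask carries over.
#' @export
odToHb <- function(od, montage, age_years = 66, coeffs = NULL) {
  stopifnot(signalUnit(od) == "optical_density")
  if (is.null(coeffs)) coeffs <- mbllCoefficients(montage, age_years)
  wl <- coeffs$wavelengths
  chans <- unique(od@channel)
  nt <- ncol(od@data)
  dat <- matrix(0, 2L * length(chans), nt)
  rown <- character(2L * length(chans))
  chn <- character(2L * length(chans))
  msk <- logical(2L * length(chans))
  for (i in seq_along(chans)) {
    ch <- chans[i]
    r1 <- which(od@channel == ch & od@wavelength == wl[1])
    r2 <- which(od@channel == ch & od@wavelength == wl[2])
    if (length(r1) != 1L || length(r2) != 1L)
      stop("channel ", ch, " lacks the two wavelength rows")
    d <- coeffs$distance_cm[[ch]]
    # A %*% c(dHbO, dHbR) = dOD, with A in OD per mM
    A <- rbind(d * coeffs$dpf[1] * coeffs$eps[, 1],
               d * coeffs$dpf[2] * coeffs$eps[, 2])
    conc <- solve(A, od@data[c(r1, r2), , drop = FALSE]) * 1000  # mM -> uM
    dat[2L * i - 1L, ] <- conc[1L, ]
    dat[2L * i, ] <- conc[2L, ]
    rown[(2L * i - 1L):(2L * i)] <- paste0(ch, "@", c("HbO", "HbR"))
    chn[(2L * i - 1L):(2L * i)] <- ch
    msk[(2L * i - 1L):(2L * i)] <- od@mask[r1] || od@mask[r2]
  }
  rownames(dat) <- rown
  fnirsRecording(dat, fs = od@fs, unit = "micromolar", channel = chn,
                 wavelength = rep(NA_real_, nrow(dat)),
                 chromophore = rep(c("HbO", "HbR"), length(chans)),
                 runId = od@runId, time0 = od@time0, mask = msk)
}

#' Forward MBLL: haemoglobin concentrations to optical density
#'
#' The exact inverse of [odToHb()]; used by the synthetic generator's
#' forward model and by round-trip tests.
#'
#' @param hb A [FnirsRecording-class] with `unit = "micromolar"` and
#'   HbO/HbR rows per channel.
#' @inheritParams odToHb
#' @return A [FnirsRecording-class] with `unit = "optical_density"` and two
#'   wavelength rows per channel.
#' @export
hbToOd <- function(hb, montage, age_years = 66, coeffs = NULL) {
  stopifnot(signalUnit(hb) == "micromolar")
  if (is.null(coeffs)) coeffs <- mbllCoefficients(montage, age_years)
  wl <- coeffs$wavelengths
  chans <- unique(hb@channel)
  dat <- matrix(0, 2L * length(chans), ncol(hb@data))
  rown <- chn <- character(2L * length(chans))
  wlv <- numeric(2L * length(chans))
  msk <- logical(2L * length(chans))
  for (i in seq_along(chans)) {
    ch <- chans[i]
    ro <- which(hb@channel == ch & hb@chromophore == "HbO")
    rr <- which(hb@channel == ch & hb@chromophore == "HbR")
    d <- coeffs$distance_cm[[ch]]
    A <- rbind(d * coeffs$dpf[1] * coeffs$eps[, 1],
               d * coeffs$dpf[2] * coeffs$eps[, 2])
    od <- A %*% (hb@data[c(ro, rr), , drop = FALSE] / 1000)
    dat[2L * i - 1L, ] <- od[1L, ]
    dat[2L * i, ] <- od[2L, ]
    rown[(2L * i - 1L):(2L * i)] <- paste0(ch, "@", wl)
    chn[(2L * i - 1L):(2L * i)] <- ch
    wlv[(2L * i - 1L):(2L * i)] <- wl
    msk[(2L * i - 1L):(2L * i)] <- hb@mask[ro] || hb@mask[rr]
  }
  rownames(dat) <- rown
  fnirsRecording(dat, fs = hb@fs, unit = "optical_density", channel = chn,
                 wavelength = wlv, chromophore = rep("n/a", nrow(dat)),
                 runId = hb@runId, time0 = hb@time0, mask = msk)
}
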