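#' @import methods
#' @include AllGenerics.R
NULL

.UNITS <- c("raw_intensity", "optical_density", "micromolar", "zscore")
.ROIS <- c("M1", "PMC", "SMA", "PFC", "PPC", "none")
.HEMIS <- c("L", "R", "mid")
.CHROMOPHORES <- c("HbO", "HbR", "n/a")

#' Optode montage: channel geometry and semantics
#'
#' Describes the source-detector channel layout of a dual-wavelength
#' continuous-wave fNIRS cap: long channels (30 mm interoptode distance)
#' sample cortex and carry a region-of-interest label; short channels
#' (10 mm) sample only superficial scalp haemodynamics and serve as
#' confound references.
#'
#' @slot channels `data.frame` with columns `id`, `source`, `detector`,
#'   `distance_mm` (10 or 30), `kind` (`"long"`/`"short"`), `roi`
#'   (`"M1"`, `"PMC"`, `"SMA"`, `"PFC"`, `"PPC"` or `"none"`) and
#'   `hemisphere` (`"L"`, `"R"`, `"mid"`).
#' @slot wavelengths Numeric of length 2, nominal wavelengths in nm.
#'
#' @seealso [defaultMontage()], [readMontage()]
#' @export
setClass("FnirsMontage",
  representation(channels = "data.frame", wavelengths = "numeric"))

setValidity("FnirsMontage", function(object) {
  ch <- object@channels
  need <- c("id", "source", "detector", "distance_mm", "kind", "roi",
            "hemisphere")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (length(object@wavelengths) != 2L || any(!is.finite(object@wavelengths)))
    return("exactly two finite wavelengths required")
  if (anyDuplicated(ch$id)) return("duplicate channel ids")
  if (!all(ch$kind %in% c("long", "short"))) return("kind must be long/short")
  if (!all(ch$roi %in% .ROIS)) return("unknown roi label")
  if (!all(ch$hemisphere %in% .HEMIS)) return("unknown hemisphere label")
  if (any(ch$kind == "long" & ch$distance_mm != 30))
    return("long channels must have interoptode distance 30 mm")
  if (any(ch$kind == "short" & ch$distance_mm != 10))
    return("short channels must have interoptode distance 10 mm")
  TRUE
})

#' Multi-channel fNIRS recording
#'
#' A uniformly sampled channel-by-sample matrix together with the metadata
#' the pipeline tracks through every stage: sampling rate, signal unit
#' (raw intensity, optical density, micromolar haemoglobin, or z-units),
#' per-row chromophore tags, the run identifier, the time origin on the
#' session clock, and the quality-control channel mask.
#'
#' Row identity follows the `"S#-D#@760"` convention for wavelength rows;
#' after conversion to haemoglobin the two wavelength rows of a channel are
#' replaced by `"S#-D#@HbO"` and `"S#-D#@HbR"` rows.
#'
#' @slot data Numeric matrix, channels x samples; rownames are row ids.
#' @slot channel Character, base channel id (`"S#-D#"`) per row.
#' @slot wavelength Numeric per row (nm); `NA` for chromophore rows.
#' @slot chromophore `"HbO"`, `"HbR"` or `"n/a"` per row.
#' @slot fs Sampling rate, Hz.
#' @slot unit Signal unit (see above).
#' @slot runId Run identifier.
#' @slot time0 Start time on the session clock, seconds.
#' @slot mask Logical per row; `TRUE` = pruned.
#'
#' @seealso [fnirsRecording()], [intensityToOd()], [odToHb()]
#' @export
setClass("FnirsRecording",
  representation(data = "matrix", channel = "character",
                 wavelength = "numeric", chromophore = "character",
                 fs = "numeric", unit = "character", runId = "character",
                 time0 = "numeric", mask = "logical"))

setValidity("FnirsRecording", function(object) {
  n <- nrow(object@data)
  if (length(object@channel) != n) return("channel tag per row required")
  if (length(object@wavelength) != n) return("wavelength tag per row required")
  if (length(object@chromophore) != n)
    return("chromophore tag per row required")
  if (length(object@mask) != n) return("mask must have one flag per row")
  if (!all(object@chromophore %in% .CHROMOPHORES))
    return("chromophore must be HbO/HbR/n/a")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a positive scalar")
  if (!object@unit %in% .UNITS)
    return(paste("unit must be one of:", paste(.UNITS, collapse = ", ")))
  if (length(object@time0) != 1L || !is.finite(object@time0))
    return("time0 must be a finite scalar")
  bad <- !is.finite(object@data[!object@mask, , drop = FALSE])
  if (any(bad)) return("non-finite values in unmasked channels")
  TRUE
})

#' Construct an FnirsRecording
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param unit Signal unit.
#' @param channel Base channel id per row (default parsed from rownames,
#'   stripping a trailing `"@..."` tag).
#' @param wavelength Wavelength (nm) per row; `NA` for chromophore rows.
#' @param chromophore `"HbO"`, `"HbR"` or `"n/a"` per row.
#' @param runId Run identifier.
#' @param time0 Time origin in seconds.
#' @param mask Logical pruned flag per row.
#' @return A [FnirsRecording-class] object.
#' @export
fnirsRecording <- function(data, fs, unit,
                           channel = sub("@.*$", "", rownames(data)),
                           wavelength = rep(NA_real_, nrow(data)),
                           chromophore = rep("n/a", nrow(data)),
                           runId = "run-01", time0 = 0,
                           mask = rep(FALSE, nrow(data))) {
  data <- as.matrix(data)
  if (is.null(rownames(data)))
    stop("data must have rownames giving row ids")
  new("FnirsRecording", data = data, channel = as.character(channel),
      wavelength = as.numeric(wavelength),
      chromophore = as.character(chromophore), fs = fs, unit = unit,
      runId = runId, time0 = as.numeric(time0), mask = mask)
}

#' Head and body kinematics
#'
#' Uniformly sampled movement series used both for indirect-movement-
#' artifact regression (head acceleration, head angular acceleration,
#' head-relative-to-neck orientation) and for kinematic gait-event
#' detection (walking velocity and planar position).
#'
#' @slot data Samples x series matrix with columns `accel_x/y/z` (m/s^2),
#'   `angacc_x/y/z` (rad/s^2), `neck_pitch/roll/yaw` (deg), `velocity`
#'   (m/s), `pos_x`, `pos_y` (m).
#' @slot fs Sampling rate, Hz (60 by default in this protocol).
#' @slot time0 Start time on the session clock, seconds.
#' @export
setClass("GaitKinematics",
  representation(data = "matrix", fs = "numeric", time0 = "numeric"))

.KIN_COLS <- c("accel_x", "accel_y", "accel_z",
               "angacc_x", "angacc_y", "angacc_z",
               "neck_pitch", "neck_roll", "neck_yaw",
               "velocity", "pos_x", "pos_y")

setValidity("GaitKinematics", function(object) {
  if (!all(.KIN_COLS %in% colnames(object@data)))
    return(paste("kinematics must have columns:",
                 paste(.KIN_COLS, collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a positive scalar")
  if (any(!is.finite(object@data))) return("non-finite kinematic samples")
  TRUE
})

#' Construct a GaitKinematics object
#'
#' @param data Samples x series matrix (see [GaitKinematics-class]).
#' @param fs Sampling rate in Hz.
#' @param time0 Time origin in seconds.
#' @return A [GaitKinematics-class] object.
#' @export
gaitKinematics <- function(data, fs = 60, time0 = 0) {
  new("GaitKinematics", data = as.matrix(data), fs = fs,
      time0 = as.numeric(time0))
}

setMethod("samplingRate", "FnirsRecording", function(x) x@fs)
setMethod("samplingRate", "GaitKinematics", function(x) x@fs)
setMethod("nSamples", "FnirsRecording", function(x) ncol(x@data))
setMethod("nSamples", "GaitKinematics", function(x) nrow(x@data))
setMethod("timeOrigin", "FnirsRecording", function(x) x@time0)
setMethod("timeOrigin", "GaitKinematics", function(x) x@time0)
setReplaceMethod("timeOrigin", "FnirsRecording", function(x, value) {
  x@time0 <- as.numeric(value); validObject(x); x
})
setReplaceMethod("timeOrigin", "GaitKinematics", function(x, value) {
  x@time0 <- as.numeric(value); validObject(x); x
})
setMethod("signalUnit", "FnirsRecording", function(x) x@unit)
setMethod("channelData", "FnirsRecording", function(x) x@data)
setMethod("channelData", "GaitKinematics", function(x) x@data)
setMethod("channelMask", "FnirsRecording", function(x) {
  stats::setNames(x@mask, rownames(x@data))
})
setReplaceMethod("channelMask", "FnirsRecording", function(x, value) {
  x@mask <- as.logical(value); validObject(x); x
})
setMethod("runId", "FnirsRecording", function(x) x@runId)

setMethod("show", "FnirsMontage", function(object) {
  ch <- object@channels
  cat("FnirsMontage:", sum(ch$kind == "long"), "long +",
      sum(ch$kind == "short"), "short channels;",
      "wavelengths", paste(object@wavelengths, collapse = "/"), "nm\n")
  tab <- table(ch$roi[ch$kind == "long"])
  cat("  long-channel ROIs:",
      paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

setMethod("show", "FnirsRecording", function(object) {
  cat("FnirsRecording", object@runId, "|", nrow(object@data), "rows x",
      ncol(object@data), "samples @", object@fs, "Hz |", object@unit, "\n")
  cat("  time0 =", object@time0, "s;", sum(object@mask), "rows pruned\n")
})

setMethod("show", "GaitKinematics", function(object) {
  cat("GaitKinematics:", nrow(object@data), "samples @", object@fs,
      "Hz; time0 =", object@time0, "s\n")
})
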