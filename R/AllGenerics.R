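#' Sampling rate of a time-series object
#'
#' @param x A [FnirsRecording-class] or [GaitKinematics-class] object.
#' @return Sampling rate in Hz (numeric scalar).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of samples per channel/series
#' @param x A time-series object.
#' @return Integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Time origin (seconds on the session clock)
#' @param x A time-series object.
#' @return Numeric scalar, seconds.
#' @export
setGeneric("timeOrigin", function(x) standardGeneric("timeOrigin"))

#' @rdname timeOrigin
#' @param value New time origin in seconds.
#' @export
setGeneric("timeOrigin<-", function(x, value) standardGeneric("timeOrigin<-"))

#' Signal unit of a recording
#' @param x A [FnirsRecording-class].
#' @return One of `"raw_intensity"`, `"optical_density"`, `"micromolar"`,
#'   `"zscore"`.
#' @export
setGeneric("signalUnit", function(x) standardGeneric("signalUnit"))

#' Channel-by-sample data matrix
#' @param x A [FnirsRecording-class] or [GaitKinematics-class].
#' @return Numeric matrix (rows = channels/series).
#' @export
setGeneric("channelData", function(x) standardGeneric("channelData"))

#' Pruned-channel mask
#'
#' Logical vector, one element per data row, `TRUE` for rows flagged as
#' pruned by quality control. Pruned rows are retained in the object (so
#' channel bookkeeping is stable) but excluded from analysis.
#'
#' @param x A [FnirsRecording-class].
#' @return Named logical vector.
#' @export
setGeneric("channelMask", function(x) standardGeneric("channelMask"))

#' @rdname channelMask
#' @param value Logical vector of length `nrow(channelData(x))`.
#' @export
setGeneric("channelMask<-", function(x, value) standardGeneric("channelMask<-"))

#' Run identifier
#' @param x A [FnirsRecording-class].
#' @return Character scalar.
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
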