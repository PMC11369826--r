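#' Write / load an fNIRS recording
#'
#' Two plain-text container dialects are supported and round-trip the same
#' object:
#' \describe{
#'   \item{`"snirf_json"`}{a single JSON document mirroring the SNIRF group
#'     hierarchy (`formatVersion`, `nirs/metaDataTags`, `nirs/data1`
#'     holding the channel-by-sample matrix and time vector,
#'     `nirs/measurementList` tagging each row with its channel,
#'     wavelength and chromophore, `nirs/probe` holding the montage).}
#'   \item{`"tsv"`}{a tab-separated matrix (`time_s` column plus one column
#'     per data row) with `#key=value` metadata header lines and the
#'     montage in a `<path>.montage.json` sidecar.}
#' }
#'
#' @param path File path.
#' @param recording A [FnirsRecording-class].
#' @param montage A [FnirsMontage-class] consistent with the recording.
#' @param format `"snirf_json"` or `"tsv"`.
#' @return `loadRecording()`: `list(recording =, montage =)`;
#'   `writeRecording()`: `path`, invisibly. Files lacking wavelength or
#'   channel metadata, and TSV files with non-uniform sampling, are
#'   rejected with an error.
#' @export
writeRecording <- function(path, recording, montage,
                           format = c("snirf_json", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(recording, "FnirsRecording"), is(montage, "FnirsMontage"))
  x <- recording
  if (format == "snirf_json") {
    obj <- list(
      formatVersion = "snirf-like-json/1.0",
      nirs = list(
        metaDataTags = list(runId = x@runId, time0_s = x@time0,
                            unit = x@unit, fs_hz = x@fs),
        data1 = list(
          dataTimeSeries = unname(x@data),
          time = x@time0 + (seq_len(ncol(x@data)) - 1) / x@fs),
        measurementList = data.frame(
          rowId = rownames(x@data), channel = x@channel,
          wavelength = x@wavelength, chromophore = x@chromophore,
          pruned = x@mask, stringsAsFactors = FALSE),
        probe = list(wavelengths = montage@wavelengths,
                     channels = montage@channels)))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", na = "null")
  } else {
    mat <- t(x@data)
    df <- data.frame(time_s = x@time0 + (seq_len(ncol(x@data)) - 1) / x@fs,
                     mat, check.names = FALSE)
    con <- file(path, "w")
    writeLines(c(sprintf("#runId=%s", x@runId),
                 sprintf("#unit=%s", x@unit),
                 sprintf("#fs_hz=%.17g", x@fs),
                 sprintf("#time0_s=%.17g", x@time0),
                 sprintf("#pruned=%s",
                         paste(rownames(x@data)[x@mask], collapse = ","))),
               con)
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    writeMontage(paste0(path, ".montage.json"), montage)
  }
  invisible(path)
}

#' @rdname writeRecording
#' @export
loadRecording <- function(path, format = c("snirf_json", "tsv")) {
  format <- match.arg(format)
  if (format == "snirf_json") {
    obj <- jsonlite::fromJSON(path)
    nirs <- obj$nirs
    if (is.null(nirs$probe$wavelengths) || length(nirs$probe$wavelengths) < 2)
      stop("recording file lacks wavelength metadata: ", path)
    if (is.null(nirs$measurementList) || is.null(nirs$probe$channels))
      stop("recording file lacks channel metadata: ", path)
    tm <- nirs$data1$time
    if (length(tm) > 2) {
      dt <- diff(tm)
      if (max(dt) - min(dt) > 1e-6 * mean(dt))
        stop("non-uniform sampling in ", path)
    }
    ml <- nirs$measurementList
    dat <- nirs$data1$dataTimeSeries
    rownames(dat) <- ml$rowId
    rec <- fnirsRecording(dat, fs = nirs$metaDataTags$fs_hz,
                          unit = nirs$metaDataTags$unit,
                          channel = ml$channel,
                          wavelength = as.numeric(ml$wavelength),
                          chromophore = ml$chromophore,
                          runId = nirs$metaDataTags$runId,
                          time0 = nirs$metaDataTags$time0_s,
                          mask = as.logical(ml$pruned))
    mon <- new("FnirsMontage",
               channels = as.data.frame(nirs$probe$channels),
               wavelengths = as.numeric(nirs$probe$wavelengths))
    return(list(recording = rec, montage = mon))
  }
  ## tsv dialect
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  meta <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, function(p)
    if (length(p) > 1) p[2] else "", ""), vapply(meta, `[`, "", 1))
  if (!all(c("fs_hz", "unit", "runId") %in% names(meta)))
    stop("tsv recording lacks metadata header lines: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  tm <- df$time_s
  if (length(tm) > 2) {
    dt <- diff(tm)
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("non-uniform sampling in ", path)
  }
  monpath <- paste0(path, ".montage.json")
  if (!file.exists(monpath))
    stop("recording file lacks channel metadata (missing sidecar ",
         monpath, ")")
  mon <- readMontage(monpath)
  dat <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  ids <- rownames(dat)
  tag <- sub("^.*@", "", ids)
  wl <- suppressWarnings(as.numeric(tag))
  chrom <- ifelse(tag %in% c("HbO", "HbR"), tag, "n/a")
  pruned <- strsplit(meta[["pruned"]], ",", fixed = TRUE)[[1]]
  rec <- fnirsRecording(dat, fs = as.numeric(meta[["fs_hz"]]),
                        unit = meta[["unit"]],
                        wavelength = wl, chromophore = chrom,
                        runId = meta[["runId"]],
                        time0 = as.numeric(meta[["time0_s"]]),
                        mask = ids %in% pruned)
  list(recording = rec, montage = mon)
}

#' Write / read kinematics as TSV
#'
#' Tab-separated text with a `time_s` column followed by the twelve
#' kinematic series, and `#fs_hz` / `#time0_s` metadata header lines.
#'
#' @param path File path.
#' @param kin A [GaitKinematics-class].
#' @return `readKinematics()`: a [GaitKinematics-class];
#'   `writeKinematics()`: `path` invisibly.
#' @export
writeKinematics <- function(path, kin) {
  df <- data.frame(time_s = kin@time0 + (seq_len(nrow(kin@data)) - 1) / kin@fs,
                   kin@data, check.names = FALSE)
  con <- file(path, "w")
  writeLines(c(sprintf("#fs_hz=%.17g", kin@fs),
               sprintf("#time0_s=%.17g", kin@time0)), con)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeKinematics
#' @export
readKinematics <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(as.numeric(vapply(meta, `[`, "", 2)),
                          vapply(meta, `[`, "", 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  gaitKinematics(as.matrix(df[, .KIN_COLS]), fs = meta[["fs_hz"]],
                 time0 = meta[["time0_s"]])
}

#' Align an fNIRS recording and kinematics onto a common clock
#'
#' Applies known synchronization offsets (from sync events recorded by the
#' acquisition setup; they are inputs here, not estimated), then crops both
#' streams to their temporal overlap so that both report the same
#' `timeOrigin()` on the common clock.
#'
#' @param recording A [FnirsRecording-class].
#' @param kin A [GaitKinematics-class].
#' @param offsets Numeric length-2 `c(fnirs, kinematics)` in seconds; each
#'   stream's clock reading plus its offset is the common-clock time.
#' @return `list(recording =, kinematics =)`, cropped to the overlap.
#'   Errors if the streams do not overlap in time.
#' @examples
#' rec <- fnirsRecording(matrix(rnorm(200), 2, 100,
#'          dimnames = list(c("S1-D1@760", "S1-D1@850"), NULL)),
#'          fs = 50, unit = "raw_intensity")
#' @export
alignStreams <- function(recording, kin, offsets = c(0, 0)) {
  stopifnot(length(offsets) == 2L, all(is.finite(offsets)))
  t0r <- recording@time0 + offsets[1]
  t0k <- kin@time0 + offsets[2]
  endr <- t0r + ncol(recording@data) / recording@fs
  endk <- t0k + nrow(kin@data) / kin@fs
  t0 <- max(t0r, t0k)
  t1 <- min(endr, endk)
  if (t1 <= t0) stop("streams have no temporal overlap")
  ir <- seq(from = 1L + round((t0 - t0r) * recording@fs),
            length.out = floor((t1 - t0) * recording@fs))
  ik <- seq(from = 1L + round((t0 - t0k) * kin@fs),
            length.out = floor((t1 - t0) * kin@fs))
  recording@data <- recording@data[, ir, drop = FALSE]
  recording@time0 <- t0
  kin@data <- kin@data[ik, , drop = FALSE]
  kin@time0 <- t0
  validObject(recording); validObject(kin)
  list(recording = recording, kinematics = kin)
}
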