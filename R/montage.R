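#' Default cap layout: 32 long + 16 short channels
#'
#' Builds the package's reference montage: 32 long channels (30 mm) covering
#' five motor/executive regions of interest over both hemispheres --
#' prefrontal cortex (PFC, 8 channels), premotor cortex (PMC, 6),
#' supplementary motor area (SMA, 4, midline), primary motor cortex (M1, 6)
#' and posterior parietal cortex (PPC, 8) -- plus 16 short channels (10 mm)
#' distributed over the cap, at nominal wavelengths 760 and 850 nm.
#'
#' @param wavelengths Numeric of length 2 (nm).
#' @return A [FnirsMontage-class] object.
#' @examples
#' m <- defaultMontage()
#' table(montageChannels(m)$kind)
#' @export
defaultMontage <- function(wavelengths = c(760, 850)) {
  roi <- c(rep("PFC", 8), rep("PMC", 6), rep("SMA", 4), rep("M1", 6),
           rep("PPC", 8))
  hemi <- c(rep(c("L", "R"), 4), rep(c("L", "R"), 3), rep("mid", 4),
            rep(c("L", "R"), 3), rep(c("L", "R"), 4))
  j <- seq_len(32)
  src <- ceiling(j / 2)
  det <- ((j - 1L) %% 8L) + 1L
  long <- data.frame(
    id = sprintf("S%d-D%d", src, det),
    source = sprintf("S%d", src), detector = sprintf("D%d", det),
    distance_mm = 30, kind = "long", roi = roi, hemisphere = hemi,
    stringsAsFactors = FALSE)
  k <- seq_len(16)
  short <- data.frame(
    id = sprintf("S%d-D%d", k, 8L + k),
    source = sprintf("S%d", k), detector = sprintf("D%d", 8L + k),
    distance_mm = 10, kind = "short", roi = "none",
    hemisphere = rep(c("L", "R"), 8), stringsAsFactors = FALSE)
  new("FnirsMontage", channels = rbind(long, short),
      wavelengths = as.numeric(wavelengths))
}

#' Montage channel table and subsets
#'
#' `montageChannels()` returns the full channel table; `longChannels()` and
#' `shortChannels()` return the base channel ids of each class; `roiOf()`
#' maps base channel ids to their ROI label.
#'
#' @param montage A [FnirsMontage-class].
#' @return `montageChannels()`: a `data.frame`; the id helpers: character
#'   vectors; `roiOf()`: named character vector.
#' @export
montageChannels <- function(montage) montage@channels

#' @rdname montageChannels
#' @export
longChannels <- function(montage)
  montage@channels$id[montage@channels$kind == "long"]

#' @rdname montageChannels
#' @export
shortChannels <- function(montage)
  montage@channels$id[montage@channels$kind == "short"]

#' @rdname montageChannels
#' @param ids Base channel ids to look up (default: all long channels).
#' @export
roiOf <- function(montage, ids = longChannels(montage)) {
  m <- match(ids, montage@channels$id)
  if (anyNA(m)) stop("unknown channel id(s): ",
                     paste(ids[is.na(m)], collapse = ", "))
  stats::setNames(montage@channels$roi[m], ids)
}

#' Read / write a montage as JSON
#'
#' The montage is serialized as a small JSON document with a `wavelengths_nm`
#' array and a `channels` record array, so fixtures stay human-readable.
#'
#' @param path File path.
#' @param montage A [FnirsMontage-class].
#' @return `readMontage()` returns a [FnirsMontage-class];
#'   `writeMontage()` returns `path` invisibly.
#' @export
writeMontage <- function(path, montage) {
  obj <- list(wavelengths_nm = montage@wavelengths,
              channels = montage@channels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname writeMontage
#' @export
readMontage <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$wavelengths_nm) || is.null(obj$channels))
    stop("montage file lacks wavelengths_nm or channels: ", path)
  new("FnirsMontage", channels = as.data.frame(obj$channels),
      wavelengths = as.numeric(obj$wavelengths_nm))
}
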