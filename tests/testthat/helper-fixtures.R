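# Shared fixture builders; everything is generated in code.

# minimal valid montage: nL long + nS short channels
tinyMontage <- function(nL = 2, nS = 1, rois = c("M1", "PFC")) {
  long <- data.frame(
    id = sprintf("S%d-D%d", seq_len(nL), seq_len(nL)),
    source = sprintf("S%d", seq_len(nL)),
    detector = sprintf("D%d", seq_len(nL)),
    distance_mm = 30, kind = "long",
    roi = rep_len(rois, nL), hemisphere = "L",
    stringsAsFactors = FALSE)
  short <- data.frame(
    id = sprintf("S%d-D%d", seq_len(nS), 90 + seq_len(nS)),
    source = sprintf("S%d", seq_len(nS)),
    detector = sprintf("D%d", 90 + seq_len(nS)),
    distance_mm = 10, kind = "short", roi = "none", hemisphere = "L",
    stringsAsFactors = FALSE)
  new("FnirsMontage", channels = rbind(long, short),
      wavelengths = c(760, 850))
}

# dual-wavelength intensity recording for a montage
tinyRecording <- function(montage, n = 500, fs = 50, seed = 1,
                          unit = "raw_intensity") {
  set.seed(seed)
  ids <- montageChannels(montage)$id
  rows <- as.vector(rbind(paste0(ids, "@760"), paste0(ids, "@850")))
  dat <- matrix(1 + 0.01 * rnorm(length(rows) * n), length(rows), n,
                dimnames = list(rows, NULL))
  fnirsRecording(dat, fs = fs, unit = unit,
                 channel = rep(ids, each = 2),
                 wavelength = rep(c(760, 850), length(ids)))
}

# single-row optical-density recording from a numeric vector
odRecording <- function(x, fs = 60, id = "S1-D1@760") {
  dat <- matrix(x, 1, length(x), dimnames = list(id, NULL))
  fnirsRecording(dat, fs = fs, unit = "optical_density",
                 wavelength = 760)
}

# kinematics with given velocity/position/pitch traces
tinyKinematics <- function(n, fs = 60, velocity = rep(1, n),
                           pos_x = cumsum(velocity) / fs,
                           neck_pitch = NULL, neck_yaw = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(neck_pitch)) neck_pitch <- rnorm(n, 0, 0.05)
  if (is.null(neck_yaw)) neck_yaw <- rnorm(n, 0, 0.05)
  dat <- cbind(accel_x = rnorm(n, 0, 0.01), accel_y = rnorm(n, 0, 0.01),
               accel_z = rnorm(n, 0, 0.01),
               angacc_x = rnorm(n, 0, 0.01), angacc_y = rnorm(n, 0, 0.01),
               angacc_z = rnorm(n, 0, 0.01),
               neck_pitch = neck_pitch, neck_roll = rnorm(n, 0, 0.01),
               neck_yaw = neck_yaw,
               velocity = velocity, pos_x = pos_x, pos_y = rep(0, n))
  gaitKinematics(dat, fs = fs)
}

# a small session shared by several expensive tests (cached per run)
sharedSession <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSession(protocolSpec(n_runs = 1), seed = 42)
    cache
  }
})
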