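#' Zero-phase Butterworth low-pass filter
#'
#' Third-order 0.5 Hz low-pass applied forward-backward to both the fNIRS
#' and the movement data before confound regression, removing heartbeats
#' and footstep rhythms. Single-pass magnitude at the cut-off is 1/sqrt(2);
#' the zero-phase application squares the magnitude response.
#'
#' @param x A [FnirsRecording-class] or [GaitKinematics-class].
#' @param fc Cut-off frequency, Hz.
#' @param order Filter order.
#' @return Object of the same class, filtered per channel/series.
#' @export
lowpassFilter <- function(x, fc = 0.5, order = 3) {
  fs <- samplingRate(x)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  if (is(x, "FnirsRecording")) {
    for (r in seq_len(nrow(x@data)))
      if (!x@mask[r]) x@data[r, ] <- .zfilt(bf, x@data[r, ])
  } else {
    for (j in seq_len(ncol(x@data)))
      x@data[, j] <- .zfilt(bf, x@data[, j])
  }
  x
}

#' Principal components of the short channels
#'
#' Pools the (unpruned) short-channel HbO and HbR rows, z-transforms each
#' row, and extracts the first `k` principal-component score time courses,
#' ordered by variance, as systemic-confound regressors. With the default
#' k = 8 these represented >90% of the short-channel variance in the study
#' this pipeline models.
#'
#' @param short A [FnirsRecording-class] containing short-channel
#'   HbO/HbR rows (micromolar or z units).
#' @param k Number of components (8). `k = 0` returns an empty block.
#' @return List: `scores` (samples x k matrix, columns `sc_pc_1..k`,
#'   z-transformed), `variance_explained` (scalar, fraction of pooled
#'   variance captured by the k components), `k_used`.
#' @export
pcaShortChannels <- function(short, k = 8) {
  rows <- which(!short@mask)
  if (k == 0 || length(rows) == 0)
    return(list(scores = matrix(0, ncol(short@data), 0),
                variance_explained = NA_real_, k_used = 0L))
  z <- t(apply(short@data[rows, , drop = FALSE], 1, .ztrans))
  keep <- apply(z, 1, function(v) any(v != 0))
  z <- z[keep, , drop = FALSE]
  if (nrow(z) < k) {
    warning("only ", nrow(z), " unpruned short rows; using all")
    k <- nrow(z)
  }
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scores <- apply(scores, 2, .ztrans)
  colnames(scores) <- sprintf("sc_pc_%d", seq_len(k))
  ve <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve, k_used = as.integer(k))
}

#' Head-movement regressors
#'
#' The nine z-transformed head-kinematic series used to regress out
#' indirect movement artifacts: 3-axis head acceleration, 3-axis head
#' angular acceleration, and the 3 head-relative-to-neck orientation
#' angles (participants look down when stopping, turning or freezing).
#' Zero-variance series are dropped with a warning.
#'
#' @param kin A [GaitKinematics-class], already low-pass filtered.
#' @return Samples x p matrix of z-transformed columns.
#' @export
buildMotionRegressors <- function(kin) {
  cols <- c("accel_x", "accel_y", "accel_z",
            "angacc_x", "angacc_y", "angacc_z",
            "neck_pitch", "neck_roll", "neck_yaw")
  m <- kin@data[, cols, drop = FALSE]
  z <- apply(m, 2, .ztrans)
  degen <- vapply(seq_len(ncol(z)), function(j) all(z[, j] == 0), TRUE)
  if (any(degen)) {
    warning("dropping zero-variance motion regressor(s): ",
            paste(cols[degen], collapse = ", "))
    z <- z[, !degen, drop = FALSE]
  }
  z
}

#' Regress systemic and movement confounds out of the long channels
#'
#' Per long channel, ordinary least squares of the channel time course on
#' the short-channel principal components and head-movement regressors
#' (plus an intercept); the residuals carry forward. Residuals are exactly
#' orthogonal to every regressor column.
#'
#' @param long A [FnirsRecording-class] of long-channel rows.
#' @param regressors Samples x p numeric matrix (combined
#'   [pcaShortChannels()] scores and [buildMotionRegressors()] columns).
#' @return List: `residuals` (a [FnirsRecording-class]) and `report`
#'   (per-row `r_squared`, `residual_variance`, and the coefficient
#'   matrix as attribute `"coefficients"`).
#' @export
regressConfounds <- function(long, regressors) {
  X <- cbind(`(intercept)` = 1, as.matrix(regressors))
  if (nrow(X) != ncol(long@data))
    stop("regressor rows must match recording samples")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    cols <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient regressor matrix; collinear columns: ",
         paste(cols, collapse = ", "))
  }
  out <- long
  rep <- data.frame(row_id = rownames(long@data),
                    r_squared = NA_real_, residual_variance = NA_real_,
                    stringsAsFactors = FALSE)
  coefs <- matrix(NA_real_, nrow(long@data), ncol(X),
                  dimnames = list(rownames(long@data), colnames(X)))
  for (r in seq_len(nrow(long@data))) {
    if (long@mask[r]) next
    y <- long@data[r, ]
    fit <- qr.coef(qx, y)
    res <- y - as.vector(X %*% fit)
    out@data[r, ] <- res
    tss <- sum((y - mean(y))^2)
    rep$r_squared[r] <- if (tss > 0) 1 - sum(res^2) / tss else 0
    rep$residual_variance[r] <- stats::var(res)
    coefs[r, ] <- fit
  }
  attr(rep, "coefficients") <- coefs
  list(residuals = out, report = rep)
}

#' Split a haemoglobin recording by montage channel class
#'
#' @param hb A [FnirsRecording-class] with chromophore rows.
#' @param montage The [FnirsMontage-class].
#' @return List with elements `long` and `short`, each a
#'   [FnirsRecording-class].
#' @export
splitByClass <- function(hb, montage) {
  ids <- montageChannels(montage)
  take <- function(kind) {
    keep <- hb@channel %in% ids$id[ids$kind == kind]
    r <- hb
    r@data <- hb@data[keep, , drop = FALSE]
    r@channel <- hb@channel[keep]
    r@wavelength <- hb@wavelength[keep]
    r@chromophore <- hb@chromophore[keep]
    r@mask <- hb@mask[keep]
    r
  }
  list(long = take("long"), short = take("short"))
}
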