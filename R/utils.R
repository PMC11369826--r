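# run expr with a locally seeded RNG, restoring global state afterwards
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% 2147483647L)
  force(expr)
}

# derive a child seed (kept below 2^31)
.childSeed <- function(seed, k) as.integer((seed * 1009 + k) %% 2147483629)

# centred moving average smoothing, width w samples
.movAvg <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill filter NAs at the edges with the nearest computed value
  idx <- which(!is.na(y))
  y[seq_len(idx[1] - 1L)] <- y[idx[1]]
  y[seq(idx[length(idx)] + 1L, length.out = length(y) - idx[length(idx)])] <-
    y[idx[length(idx)]]
  y
}

# z-transform a vector; returns zeros (with attr) if degenerate
.ztrans <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(structure(rep(0, length(x)),
                                               degenerate = TRUE))
  (x - mean(x)) / s
}

# zero-phase (forward-backward) filtering with steady-state initial
# conditions, so constant and slowly varying signals carry no edge
# transient (the plain filtfilt zero-state start does not settle within
# a run for 0.01 Hz high-pass filters)
.zfilt <- function(bf, x) {
  g0 <- sum(bf$b) / sum(bf$a)          # DC gain
  k <- max(length(bf$a), length(bf$b)) - 1L
  run <- function(v)
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], k),
                              init.y = rep(v[1] * g0, k)))
  rev(run(rev(run(x))))
}
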