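# Daubechies-2 (4-tap) discrete wavelet transform, periodized.
# Used by the wavelet motion-artifact correction; detail coefficients far
# outside the interquartile fences are treated as artifact and zeroed.

.DB2_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.DB2_G <- c(.DB2_H[4], -.DB2_H[3], .DB2_H[2], -.DB2_H[1])

# one analysis level (x length must be even)
.dwtStep <- function(x) {
  n <- length(x)
  xx <- c(x, x[1:2])            # periodic extension
  ev <- seq(1, n, by = 2)
  a <- .DB2_H[1] * xx[ev] + .DB2_H[2] * xx[ev + 1] +
    .DB2_H[3] * xx[ev + 2] + .DB2_H[4] * xx[ev + 3]
  d <- .DB2_G[1] * xx[ev] + .DB2_G[2] * xx[ev + 1] +
    .DB2_G[3] * xx[ev + 2] + .DB2_G[4] * xx[ev + 3]
  list(a = a, d = d)
}

# one synthesis level (transpose of the analysis step):
# x[2t-1] = h1 a[t] + h3 a[t-1] + g1 d[t] + g3 d[t-1]
# x[2t]   = h2 a[t] + h4 a[t-1] + g2 d[t] + g4 d[t-1],  a[0] = a[m]
.idwtStep <- function(a, d) {
  m <- length(a)
  ap <- c(a[m], a[-m]); dp <- c(d[m], d[-m])
  out <- numeric(2 * m)
  out[seq(1, 2 * m, 2)] <- .DB2_H[1] * a + .DB2_H[3] * ap +
    .DB2_G[1] * d + .DB2_G[3] * dp
  out[seq(2, 2 * m, 2)] <- .DB2_H[2] * a + .DB2_H[4] * ap +
    .DB2_G[2] * d + .DB2_G[4] * dp
  out
}

# full periodized DWT to `levels` levels (n must be divisible by 2^levels)
.dwt <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- .dwtStep(a)
    a <- s$a
    details[[j]] <- s$d
  }
  list(approx = a, details = details)
}

.idwt <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) a <- .idwtStep(a, w$details[[j]])
  a
}

# symmetric-pad a signal to the next multiple of 2^levels
.padPow2 <- function(x, levels) {
  n <- length(x)
  block <- 2^levels
  m <- ceiling(n / block) * block
  if (m == n) return(list(x = x, n = n))
  pad <- m - n
  ref <- x[seq(n, by = -1, length.out = min(pad, n))]
  ref <- rep_len(ref, pad)
  list(x = c(x, ref), n = n)
}
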