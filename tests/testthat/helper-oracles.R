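# Independent natural-cubic-spline oracle: sets up and solves the full
# (dense) linear system for the knot second derivatives with zero curvature
# at the boundaries, then evaluates the piecewise cubic directly. Linear
# extrapolation beyond the boundary knots uses the boundary slope.
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  M <- numeric(n) # second derivatives; M[1] = M[n] = 0 (natural)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    b <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      r <- i - 1
      A[r, r] <- (h[i - 1] + h[i]) / 3
      if (r > 1) A[r, r - 1] <- h[i - 1] / 6
      if (r < n - 2) A[r, r + 1] <- h[i] / 6
      b[r] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
    }
    M[2:(n - 1)] <- solve(A, b)
  }
  eval1 <- function(t) {
    if (t <= x[1]) {
      s1 <- (y[2] - y[1]) / h[1] - h[1] / 6 * (2 * M[1] + M[2])
      return(y[1] + s1 * (t - x[1]))
    }
    if (t >= x[n]) {
      sn <- (y[n] - y[n - 1]) / h[n - 1] +
        h[n - 1] / 6 * (M[n - 1] + 2 * M[n])
      return(y[n] + sn * (t - x[n]))
    }
    i <- findInterval(t, x, rightmost.closed = TRUE)
    hi <- h[i]
    M[i] * (x[i + 1] - t)^3 / (6 * hi) +
      M[i + 1] * (t - x[i])^3 / (6 * hi) +
      (y[i] / hi - M[i] * hi / 6) * (x[i + 1] - t) +
      (y[i + 1] / hi - M[i + 1] * hi / 6) * (t - x[i])
  }
  vapply(xout, eval1, numeric(1))
}

# brute-force type-7 percentile: locate the fractional order statistic and
# interpolate between its neighbours by hand
percentile_oracle <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  k <- 1 + (n - 1) * p / 100
  lo <- floor(k); hi <- ceiling(k)
  s[lo] + (k - lo) * (s[hi] - s[lo])
}
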