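# log-log interpolation with end-slope extrapolation; x must be increasing
.loglog_interp <- function(y, x, x0) {
  lx <- log(x); ly <- log(y)
  k <- length(lx)
  vapply(x0, function(z) {
    l0 <- log(z)
    if (l0 <= lx[1]) {
      s <- (ly[2] - ly[1]) / (lx[2] - lx[1])
      return(exp(ly[1] + s * (l0 - lx[1])))
    }
    if (l0 >= lx[k]) {
      s <- (ly[k] - ly[k - 1]) / (lx[k] - lx[k - 1])
      return(exp(ly[k] + s * (l0 - lx[k])))
    }
    exp(stats::approx(lx, ly, xout = l0)$y)
  }, numeric(1))
}
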