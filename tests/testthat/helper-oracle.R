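# Exhaustive reference search for the best circular arc, independent of
# the package's scan: enumerates every arc (i, j] with both the arc and
# its complement holding >= min_width points and computes the two-sample
# t-like statistic from raw means.  Iteration order (arc length, then
# offset, strict improvement) mirrors the implementation's tie-break.
oracle_max_arc <- function(x, min_width = 2) {
  n <- length(x)
  s <- sd(x)
  best <- -Inf
  bi <- bj <- NA_integer_
  for (k in min_width:(n - min_width)) {
    for (i in 0:(n - k)) {
      arc <- x[(i + 1):(i + k)]
      rest <- x[-((i + 1):(i + k))]
      st <- abs(mean(arc) - mean(rest)) / (s * sqrt(1 / k + 1 / (n - k)))
      if (st > best) {
        best <- st
        bi <- i
        bj <- i + k
      }
    }
  }
  list(stat = best, i = bi, j = bj)
}
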