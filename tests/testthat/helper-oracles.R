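# Independent brute-force oracles used to validate the implementation.

# exact binomial upper tail by direct summation
bfBinomUpperTail <- function(k, n, p) {
  if (k > n) return(0)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# BH step-up by its definition: q_i = min over { m p_(j) / j : p_(j) >= p_i }
bfBH <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    min(1, min((m * ps / seq_len(m))[ps >= pi - 1e-15]))
  }, 0)
}

# exhaustive penalized segmentation: minimum cost over all 2^(n-1)
# placements of changepoints
bfSegmentCost <- function(y, penalty) {
  n <- length(y)
  sse <- function(v) sum((v - mean(v))^2)
  if (n == 1L) return(0)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    bounds <- c(0L, cps, n)
    cost <- penalty * length(cps)
    for (j in seq_len(length(bounds) - 1L)) {
      cost <- cost + sse(y[(bounds[j] + 1L):bounds[j + 1L]])
    }
    if (cost < best) best <- cost
  }
  best
}
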