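# Independent oracles and small fixture builders shared across tests.

# Exhaustive O(N*M) nearest-neighbor mean distance (meters in, mm out).
bruteForceSurrogate <- function(query, ref) {
  d <- vapply(seq_len(nrow(query)), function(i)
    min(sqrt(colSums((t(ref) - query[i, ])^2))), numeric(1))
  1000 * mean(d)
}

# Normal-equations polynomial OLS (raw powers, solve()).
bruteForcePolyFit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Flat horizontal grid patch at a given height (meters).
flatGrid <- function(spacingMm = 1, halfSpanMm = 10, heightMm = 0) {
  g <- seq(-halfSpanMm, halfSpanMm, by = spacingMm) / 1000
  xy <- as.matrix(expand.grid(x = g, y = g))
  cbind(xy, z = heightMm / 1000)
}

# Solid rectangular mask with 0-based half-open pixel ranges.
solidMask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(0L, nr, nc)
  m[(r0 + 1L):r1, (c0 + 1L):c1] <- 1L
  m
}

# A noiseless synthetic session: y = f(x) over a sampled surrogate sweep.
makeSession <- function(id, x, y, timestamps = seq_along(x) - 1) {
  SessionData(id, timestamps, x, y)
}
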