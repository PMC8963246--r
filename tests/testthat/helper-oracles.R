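# Independent brute-force oracles used across the unit tests. These stay
# deliberately naive (lm fits, explicit loops) so they share no code path
# with the implementation they check.

oracle_ols <- function(segment) {
  i <- seq_along(segment)
  co <- unname(coef(lm(segment ~ i)))
  list(m = co[2], b = co[1])
}

oracle_detrended_cov <- function(Xseg, Yseg, divisor) {
  tx <- oracle_ols(Xseg)
  ty <- oracle_ols(Yseg)
  acc <- 0
  for (i in seq_along(Xseg)) {
    acc <- acc + (Xseg[i] - tx$m * i - tx$b) * (Yseg[i] - ty$m * i - ty$b)
  }
  acc / divisor
}

# blocked F^2 at one scale by explicit per-window looping
oracle_blocked_f2 <- function(x, y, s, divisor = s) {
  X <- cumsum(x); Y <- cumsum(y)
  nw <- length(X) %/% s
  vals <- numeric(nw)
  for (j in seq_len(nw)) {
    idx <- ((j - 1) * s + 1):(j * s)
    vals[j] <- oracle_detrended_cov(X[idx], Y[idx], divisor)
  }
  mean(vals)
}

# helper sums of one window pair of integrated profiles, accumulated the
# slow way
helpers_of <- function(Xseg, Yseg) {
  i <- seq_along(Xseg)
  list(sx = sum(Xseg), sy = sum(Yseg),
       sxi = sum(i * Xseg), syi = sum(i * Yseg),
       sxy = sum(Xseg * Yseg),
       sx2 = sum(Xseg^2), sy2 = sum(Yseg^2))
}

# short correlated random-walk pair for engine tests
rand_pair <- function(n, seed) {
  set.seed(seed)
  z <- rnorm(n)
  list(x = 0.7 * z + 0.3 * rnorm(n), y = 0.7 * z + 0.3 * rnorm(n))
}
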