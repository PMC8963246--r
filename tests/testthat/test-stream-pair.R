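test_that("trend coefficients from helper sums equal the two-pass fit", {
  X <- 3 * (1:8) - 2
  h <- helpers_of(X, X)
  tr <- trend_from_helpers(h$sx, h$sxi, 8)
  expect_equal(tr$m, 3)
  expect_equal(tr$b, -2)
  h <- helpers_of(rep(5, 16), rep(5, 16))
  tr <- trend_from_helpers(h$sx, h$sxi, 16)
  expect_equal(tr$m, 0)
  expect_equal(tr$b, 5)
  set.seed(13)
  Xs <- cumsum(rnorm(32))
  h <- helpers_of(Xs, Xs)
  expect_equal(trend_from_helpers(h$sx, h$sxi, 32), ols_trend(Xs),
               tolerance = 1e-10)
  expect_error(trend_from_helpers(1, 1, 1), "cannot be detrended")
})

test_that("one-pass window covariance equals the brute-force residual form", {
  line <- 2 * (1:8) + 1
  expect_equal(f2_from_helpers(helpers_of(line, line), 8), 0,
               tolerance = 1e-12)
  set.seed(14)
  for (r in 1:10) {
    Xs <- cumsum(rnorm(8)); Ys <- cumsum(rnorm(8))
    h <- helpers_of(Xs, Ys)
    expect_equal(f2_from_helpers(h, 8),
                 detrended_cov(Xs, Ys, norm = "s"), tolerance = 1e-10)
    # auto case collapses to the one-pass DFA form
    ha <- helpers_of(Ys, Ys)
    expect_equal(f2_from_helpers(ha, 8),
                 f2_dfa_from_helpers(ha, 8), tolerance = 1e-12)
  }
})

test_that("one-pass DFA window term is the mean squared residual, never negative", {
  set.seed(15)
  for (r in 1:200) {
    s <- sample(c(4, 8, 16), 1)
    Ys <- cumsum(rnorm(s, sd = runif(1, 0.1, 10)))
    h <- helpers_of(Ys, Ys)
    f2 <- f2_dfa_from_helpers(h, s)
    expect_gte(f2, -1e-12)
    tr <- oracle_ols(Ys)
    expect_equal(f2, mean((Ys - tr$m * seq_len(s) - tr$b)^2),
                 tolerance = 1e-8)
  }
})

test_that("window bookkeeping fires at the documented sample counts", {
  sc <- scale_set(8, 64, W = 256)
  st <- dcca_stream(sc)
  p <- rand_pair(256, seed = 16)
  stream_push(st, p$x[1:7], p$y[1:7])
  expect_equal(unname(stream_windows(st)), c(0, 0, 0, 0))
  stream_push(st, p$x[8], p$y[8])           # first s_min window fills at t = 8
  expect_equal(unname(stream_windows(st)), c(1, 0, 0, 0))
  stream_push(st, p$x[9:16], p$y[9:16])     # t = 16: windows at 8 and 16 fill
  expect_equal(unname(stream_windows(st)), c(2, 1, 0, 0))
  expect_null(stream_estimate(st))          # warm-up: no estimate before W
  out <- stream_push(st, p$x[17:256], p$y[17:256])
  expect_length(out, 1L)                    # first emission exactly at t = W
  expect_equal(out[[1]]$t, 256)
  # every scale contributed exactly W/s windows
  expect_equal(unname(stream_windows(st)), 256 / sc$scales)
})

test_that("with W = N the stream reproduces the blocked offline estimate", {
  p <- rand_pair(1024, seed = 17)
  sc <- dyadic_preset(1024)
  est <- {
    st <- dcca_stream(sc)
    stream_push(st, p$x, p$y)
    stream_estimate(st)
  }
  expect_equal(est$F2_xy, unname(dcca_blocked(p$x, p$y, sc)),
               tolerance = 1e-10)
  expect_equal(est$F2_x, unname(dfa_blocked(p$x, sc)), tolerance = 1e-10)
  expect_equal(est$rho, unname(dccc(p$x, p$y, sc)), tolerance = 1e-10)
})

test_that("streaming estimates are invariant to how samples are chunked", {
  p <- rand_pair(1280, seed = 18)
  sc <- scale_set(8, 128, W = 512)
  one <- dcca_stream(sc)
  for (t in seq_len(1280)) stream_push(one, p$x[t], p$y[t])
  chunked <- dcca_stream(sc)
  set.seed(99)
  done <- 0
  while (done < 1280) {
    n <- min(sample(1:200, 1), 1280 - done)
    stream_push(chunked, p$x[done + 1:n], p$y[done + 1:n])
    done <- done + n
  }
  expect_identical(stream_estimate(one), stream_estimate(chunked))
})

test_that("pushing a series against itself reduces to DFA", {
  p <- rand_pair(512, seed = 19)
  st <- dcca_stream(scale_set(8, 128, W = 512))
  stream_push(st, p$x, p$x)
  est <- stream_estimate(st)
  expect_equal(est$F2_xy, est$F2_x, tolerance = 1e-12)
  expect_equal(est$rho, rep(1, 5), tolerance = 1e-12)
})

test_that("state size is fixed by the scale set, not by samples seen", {
  sc <- scale_set(8, 64, W = 256)
  size_after <- function(n) {
    st <- dcca_stream(sc)
    p <- rand_pair(n, seed = 20)
    stream_push(st, p$x, p$y)
    st$last <- NULL       # compare accumulator footprint only
    sum(vapply(ls(st), function(nm) object.size(get(nm, envir = st)), 0))
  }
  expect_identical(size_after(256), size_after(1280))
})

test_that("non-finite samples are rejected with their stream index", {
  st <- dcca_stream(scale_set(8, 64, W = 256))
  stream_push(st, 1:10, 1:10)
  expect_error(stream_push(st, c(1, NaN), c(1, 2)), "index 12")
  expect_error(stream_push(st, 1, Inf), "index 11")
  expect_error(stream_push(st, 1:3, 1:2), "differ in length")
  expect_error(dcca_stream(scale_set(8, 128, W = 500)), "multiple")
})
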