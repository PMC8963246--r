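test_that("autoregressive weights follow the gamma-ratio closed form", {
  for (d in c(0.1, 0.3, 0.45)) {
    w <- arfima_weights(d, 50)
    expect_equal(w[1], d)                       # a_1(d) = d exactly
    n <- 1:20                                   # direct Gamma ratio, small n
    expect_equal(w[1:20], d * gamma(n - d) / (gamma(1 - d) * gamma(n + 1)),
                 tolerance = 1e-12)
    expect_true(all(diff(w) < 0) && all(w > 0)) # monotone positive decay
  }
  expect_identical(arfima_weights(0, 10), numeric(10))
  expect_error(arfima_weights(0.5, 10), "lie in")
  expect_error(arfima_weights(-0.1, 10), "lie in")
})

test_that("ARFIMA simulation is reproducible and white in the d = 0 limit", {
  expect_identical(simulate_arfima(256, 0.3, seed = 5),
                   simulate_arfima(256, 0.3, seed = 5))
  expect_false(identical(simulate_arfima(256, 0.3, seed = 5),
                         simulate_arfima(256, 0.3, seed = 6)))
  # d = 0 passes the innovations through untouched
  eps <- rnorm(256 + 64)
  expect_identical(simulate_arfima(256, 0, burn_in = 64, n_trunc = 64,
                                   innovations = eps),
                   eps[65:320])
  expect_error(simulate_arfima(32, 0.3), "at least 64")
})

test_that("DFA exponents recover alpha = 0.5 + d across memory strengths", {
  sc <- dyadic_preset(8192)$scales
  for (d in c(0, 0.2, 0.4)) {
    alphas <- vapply(1:50, function(r) {
      x <- simulate_arfima(8192, d, seed = 1000 * d + r)
      fit_exponent(sc, sqrt(dfa_blocked(x, sc)))
    }, 0)
    expect_lt(abs(mean(alphas) - (0.5 + d)), 0.05)
  }
})

test_that("the mc-ARFIMA pair is reproducible and decorrelates without rho23", {
  p1 <- simulate_mc_arfima(512, seed = 31)
  p2 <- simulate_mc_arfima(512, seed = 31)
  expect_identical(p1, p2)
  # independent innovations: sample cross-correlation near zero
  pars0 <- mc_arfima_params(rho23 = 0)
  cors <- vapply(1:30, function(r) {
    p <- simulate_mc_arfima(1024, pars0, seed = r)
    cor(p$x, p$y)
  }, 0)
  expect_lt(abs(mean(cors)), 0.05)
  # correlated innovations push the raw correlation well up
  cors9 <- vapply(1:30, function(r) {
    p <- simulate_mc_arfima(1024, seed = r)
    cor(p$x, p$y)
  }, 0)
  expect_gt(mean(cors9), 0.5)
  expect_error(mc_arfima_params(d2 = 0.6), "lie in")
  expect_error(mc_arfima_params(rho23 = 1.2), "positive semi-definite")
})

test_that("swapping the component roles swaps the two series exactly", {
  M <- 512 + 512            # N + burn-in at n_trunc = min(N, 1000) = 512
  set.seed(33)
  Z <- matrix(rnorm(4 * M), M, 4)
  # uncorrelated innovations so the component relabelling is exact
  pars <- mc_arfima_params(w1 = 0.3, w2 = 0.9, w3 = 0.8, w4 = 0.1,
                           d1 = 0.35, d2 = 0.2, d3 = 0.25, d4 = 0.15,
                           rho23 = 0)
  swapped <- mc_arfima_params(w1 = 0.1, w2 = 0.8, w3 = 0.9, w4 = 0.3,
                              d1 = 0.15, d2 = 0.25, d3 = 0.2, d4 = 0.35,
                              rho23 = 0)
  a <- simulate_mc_arfima(512, pars, innovations = Z)
  b <- simulate_mc_arfima(512, swapped, innovations = Z[, 4:1])
  expect_equal(a$x, b$y, tolerance = 1e-12)
  expect_equal(a$y, b$x, tolerance = 1e-12)
})

test_that("white-noise contamination realizes the stated SNR", {
  set.seed(34)
  x <- simulate_mc_arfima(2048, seed = 35)$x
  v <- var(x)
  # realized added-noise variance across seeds matches var(x)/snr
  for (snr in c(1, 10)) {
    nv <- vapply(1:100, function(r)
      var(add_white_noise(x, snr, seed = r) - x), 0)
    expect_equal(mean(nv), v / snr, tolerance = 0.05 * v / snr)
  }
  # variance additivity of the contaminated series
  vo <- vapply(1:100, function(r) var(add_white_noise(x, 1, seed = r)), 0)
  expect_equal(mean(vo), 2 * v, tolerance = 0.1 * v)
  expect_error(add_white_noise(rep(1, 100), 10), "constant")
  expect_error(add_white_noise(x, 0), "positive")
})

test_that("spike contamination honours type, amplitude and placement rules", {
  set.seed(36)
  x <- rnorm(1024); y <- rnorm(1024)
  outA <- add_spikes(x, y, spike_spec(type = "A"), seed = 1)
  expect_identical(outA$y, y)                   # Type A: y untouched
  expect_false(identical(outA$x, x))
  expect_null(outA$positions_y)
  # peak of each bump sits amplitude * var(host) above the original
  dx <- outA$x - x
  expect_equal(max(dx), 4 * var(x) * max(0.5 * (1 - cos(2 * pi * (0:19) / 19))),
               tolerance = 1e-12)
  # non-overlap: spike starts at least one width apart
  expect_true(all(diff(sort(outA$positions_x)) >= 20))
  # Type C: same placements; equal added component when variances match
  y2 <- sample(x)                               # same variance, different order
  outC <- add_spikes(x, y2, spike_spec(type = "C"), seed = 2)
  expect_identical(outC$positions_x, outC$positions_y)
  expect_equal(outC$x - x, outC$y - y2, tolerance = 1e-12)
  # Type B: independent placements in both
  outB <- add_spikes(x, y, spike_spec(type = "B"), seed = 3)
  expect_false(identical(outB$positions_x, outB$positions_y))
  expect_false(identical(outB$y, y))
  expect_error(add_spikes(x[1:100], y[1:100], spike_spec()), "cannot place")
})
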