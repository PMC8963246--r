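test_that("matrix window term equals the pairwise closed form elementwise", {
  set.seed(23)
  for (r in 1:5) {
    s <- 8
    segs <- replicate(3, cumsum(rnorm(s)))
    h <- list(sx = colSums(segs),
              sxi = as.numeric(crossprod(seq_len(s), segs)),
              sx2 = crossprod(segs))
    f2 <- f2_matrix_from_helpers(h, s)
    expect_equal(f2, t(f2))                          # symmetric
    for (a in 1:3) for (b in 1:3) {
      hp <- helpers_of(segs[, a], segs[, b])
      expect_equal(f2[a, b], f2_from_helpers(hp, s), tolerance = 1e-12)
    }
    expect_true(all(diag(f2) >= -1e-12))
  }
  # all channels exactly linear: zero matrix
  lin <- outer(1:8, c(1, 2, 3)) + rep(c(0, 1, -2), each = 8)
  h <- list(sx = colSums(lin), sxi = as.numeric(crossprod(1:8, lin)),
            sx2 = crossprod(lin))
  expect_equal(f2_matrix_from_helpers(h, 8), matrix(0, 3, 3),
               tolerance = 1e-10)
})

test_that("a K = 2 matrix stream matches the pairwise engine bit for bit", {
  p <- rand_pair(1024, seed = 24)
  sc <- scale_set(8, 128, W = 512)
  pw <- dcca_stream(sc); stream_push(pw, p$x, p$y)
  mx <- dcca_stream_multi(2, sc); stream_push(mx, cbind(p$x, p$y))
  est <- stream_estimate(pw); em <- stream_estimate(mx)
  expect_identical(em$F2[1, 2, ], unname(est$F2_xy))
  expect_identical(em$F2[2, 1, ], unname(est$F2_xy))
  expect_identical(em$F2[1, 1, ], unname(est$F2_x))
  expect_identical(em$F2[2, 2, ], unname(est$F2_y))
  expect_identical(em$rho[1, 2, ], unname(est$rho))
  expect_identical(em$alpha, c(est$alpha_x, est$alpha_y))
  # both channel orders
  mx2 <- dcca_stream_multi(2, sc); stream_push(mx2, cbind(p$y, p$x))
  em2 <- stream_estimate(mx2)
  expect_identical(em2$F2[2, 1, ], unname(est$F2_xy))
  expect_identical(em2$F2[2, 2, ], unname(est$F2_x))
})

test_that("matrix estimates stay symmetric with DFA terms on the diagonal", {
  set.seed(25)
  n <- 768
  X <- matrix(rnorm(4 * n), ncol = 4)
  X[, 3] <- 0.5 * X[, 1] + 0.5 * X[, 3]
  sc <- scale_set(8, 64, W = 256)
  st <- dcca_stream_multi(4, sc)
  ests <- stream_push(st, X)
  expect_length(ests, (n - 256) / 64 + 1)
  for (est in ests) {
    for (q in seq_along(est$scales)) {
      expect_identical(est$F2[, , q], t(est$F2[, , q]))
      expect_true(all(diag(est$F2[, , q]) >= 0))
      expect_equal(diag(est$rho[, , q]), rep(1, 4))
      expect_true(all(abs(est$rho[, , q]) <= 1 + 1e-12))
    }
  }
  # diagonal equals an independent per-channel DFA stream
  one <- dcca_stream(sc)
  stream_push(one, X[, 2], X[, 2])
  expect_identical(stream_estimate(st)$F2[2, 2, ],
                   unname(stream_estimate(one)$F2_x))
})

test_that("duplicated channels give unit coefficients; constants are flagged", {
  set.seed(26)
  x <- rnorm(512)
  sc <- scale_set(8, 64, W = 512)
  st <- dcca_stream_multi(3, sc)
  stream_push(st, cbind(x, x, rnorm(512)))
  em <- stream_estimate(st)
  expect_equal(em$rho[1, 2, ], rep(1, sc$n_s), tolerance = 1e-12)
  # constant channel: its pairs undefined, others untouched
  st2 <- dcca_stream_multi(3, sc)
  stream_push(st2, cbind(x, rep(2, 512), rnorm(512)))
  em2 <- stream_estimate(st2)
  expect_true(all(is.na(em2$rho[2, , ])))
  expect_true(all(is.na(em2$rho[, 2, ])))
  expect_true(is.na(em2$alpha[2]))
  expect_true(all(is.finite(em2$rho[c(1, 3), c(1, 3), ])))
  expect_true(all(is.finite(em2$alpha[c(1, 3)])))
})

test_that("K = 1 tracks univariate DFA; invalid configs are rejected", {
  set.seed(27)
  x <- rnorm(512)
  sc <- scale_set(8, 64, W = 256)
  st <- dcca_stream_multi(1, sc)
  stream_push(st, matrix(x, ncol = 1))
  em <- stream_estimate(st)
  expect_equal(em$F2[1, 1, ], unname(dfa_blocked(x[257:512], sc$scales)),
               tolerance = 1e-9)
  expect_error(dcca_stream_multi(0, sc), "positive integer")
  st3 <- dcca_stream_multi(3, sc)
  expect_error(stream_push(st3, matrix(1, 2, 2)), "expects K = 3")
  expect_error(stream_push(st3, c(1, NA, 2)), "non-finite")
})

test_that("antiphase channels give exactly -1 and dccc_from_f2 round-trips", {
  set.seed(28)
  x <- rnorm(512)
  sc <- scale_set(8, 128, W = 512)
  st <- dcca_stream_multi(2, sc)
  stream_push(st, cbind(x, -x))
  em <- stream_estimate(st)
  expect_equal(em$rho[1, 2, ], rep(-1, sc$n_s))
  # rebuilding the coefficient array from F2 reproduces the estimate
  re <- dccc_from_f2(em$F2, sc$scales)
  expect_identical(re$rho, em$rho)
  expect_identical(re$alpha, em$alpha)
})

test_that("a K = 3 stream agrees with the offline coefficient pair by pair", {
  sc <- dyadic_preset(1024)
  pars <- mc_arfima_params()
  p1 <- simulate_mc_arfima(1024, pars, seed = 29)
  p2 <- simulate_mc_arfima(1024, pars, seed = 30)
  X <- cbind(p1$x, p1$y, p2$x)
  st <- dcca_stream_multi(3, sc)
  stream_push(st, X)
  em <- stream_estimate(st)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(em$rho[a, b, ], unname(dccc(X[, a], X[, b], sc)),
                 tolerance = 1e-10)
  }
})
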