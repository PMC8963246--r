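#' Streaming DCCA engine for K channels (matrix form)
#'
#' Multichannel generalization of [dcca_stream()]: the per-scale helper
#' sums become length-`K` vectors (profile and index-weighted sums) plus a
#' `K x K` accumulated outer-product matrix per scale, so that every
#' window completion yields the full symmetric `K x K` matrix of window
#' detrended covariances at once. Diagonal entries are the univariate DFA
#' window terms of each channel, hence one pass produces all pairwise
#' \eqn{F^2_{DCCA}(i,j,s)}, every channel's \eqn{F^2_{DFA}(s)} and DFA
#' exponent \eqn{\alpha}, and the full coefficient array
#' \eqn{\rho_{DCCA}(i,j,s)}.
#'
#' Per-sample operation count is fixed by `K` and the scale set; state
#' memory grows as `K^2` but never with the number of samples seen.
#'
#' @param K number of channels (`K >= 1`).
#' @param scales a [scale_set()].
#' @param channels optional channel names (length `K`).
#' @return An object of class `"dcca_stream_multi"` (mutable state handle).
#' @examples
#' st <- dcca_stream_multi(3, scale_set(8, 64, W = 256))
#' set.seed(1)
#' stream_push(st, matrix(rnorm(256 * 3), ncol = 3))
#' dim(stream_estimate(st)$rho)  # 3 x 3 x n_s
#' @export
dcca_stream_multi <- function(K, scales = scale_set(), channels = NULL) {
  if (length(K) != 1L || !is.finite(K) || K < 1 || K != round(K))
    stopf("K must be a positive integer channel count")
  K <- as.integer(K)
  sc <- if (inherits(scales, "scale_set")) scales else
    scale_set(W = 4 * max(scales), scales = scales)
  if (!is.null(channels) && length(channels) != K)
    stopf("channel names must have length K = %d", K)
  e <- new.env(parent = emptyenv())
  e$sc <- sc
  e$K <- K
  e$channels <- channels %||% paste0("ch", seq_len(K))
  ns <- sc$n_s
  e$t <- 0
  e$X <- numeric(K)
  e$sx <- matrix(0, K, ns)
  e$sxi <- matrix(0, K, ns)
  e$sx2 <- matrix(0, K * K, ns)
  e$blk <- numeric(K * K * ns)                  # flat K*K*ns block sums
  e$ring <- matrix(0, K * K * ns, sc$n_blocks)
  e$blocks_seen <- 0
  e$nwin <- numeric(ns)
  e$last <- NULL
  class(e) <- "dcca_stream_multi"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dcca_stream_multi <- function(x, ...) {
  cat(sprintf("streaming matrix DCCA engine: K = %d channels, %d scales %g..%g, W = %g; %g samples seen\n",
              x$K, x$sc$n_s, x$sc$s_min, x$sc$s_max, x$sc$W, x$t))
  invisible(x)
}

#' @rdname stream_push
#' @export
stream_push.dcca_stream_multi <- function(stream, x, ...) {
  e <- stream
  K <- e$K
  if (is.null(dim(x))) {
    if (length(x) %% K != 0)
      stopf("sample vector length %d is not a multiple of K = %d", length(x), K)
    x <- matrix(x, ncol = K, byrow = TRUE)
  }
  if (ncol(x) != K) stopf("chunk has %d columns; engine expects K = %d", ncol(x), K)
  bad <- which(!is.finite(x))
  if (length(bad))
    stopf("non-finite sample at stream index %g", e$t + (bad[1L] - 1L) %% nrow(x) + 1L)
  sc <- e$sc
  scl <- sc$scales
  ns <- sc$n_s
  smax <- sc$s_max
  nblk <- sc$n_blocks
  W <- sc$W
  KK <- K * K
  emitted <- list()
  for (k in seq_len(nrow(x))) {
    X <- e$X <- e$X + x[k, ]
    t <- e$t <- e$t + 1
    i <- (t - 1) %% scl + 1
    e$sx <- e$sx + X
    e$sxi <- e$sxi + outer(X, i)
    e$sx2 <- e$sx2 + as.vector(X %o% X)
    done <- which(i == scl)
    for (q in done) {
      s <- scl[q]
      sxq <- e$sx[, q]
      sxiq <- e$sxi[, q]
      m <- -6 * (-2 * sxiq + (s + 1) * sxq) / (s * (s^2 - 1))
      b <- sxq / s - m * (s + 1) / 2
      cc <- s * s / 3 + s / 2 + 1 / 6
      hs <- (s + 1) / 2
      S2 <- matrix(e$sx2[, q], K, K)
      M1 <- m %o% sxiq
      B1 <- b %o% sxq
      Mb <- m %o% b
      f2 <- (S2 - (M1 + t(M1)) - (B1 + t(B1))) / s +
        cc * (m %o% m) + hs * (Mb + t(Mb)) + b %o% b
      idx <- (q - 1L) * KK + seq_len(KK)
      e$blk[idx] <- e$blk[idx] + as.vector(f2)
      e$nwin[q] <- e$nwin[q] + 1
      e$sx[, q] <- 0
      e$sxi[, q] <- 0
      e$sx2[, q] <- 0
    }
    if (t %% smax == 0) {
      pos <- e$blocks_seen %% nblk + 1
      e$ring[, pos] <- e$blk
      e$blk[] <- 0
      e$blocks_seen <- e$blocks_seen + 1
      if (t >= W) {
        F2 <- .rowSums(e$ring, KK * ns, nblk) /
          rep(sc$wins_per_scale, each = KK)
        dim(F2) <- c(K, K, ns)
        est <- dccc_from_f2(F2, scl, channels = e$channels)
        est$t <- t
        e$last <- est
        emitted[[length(emitted) + 1L]] <- est
      }
    }
  }
  invisible(emitted)
}

#' Matrix of window detrended covariances from helper sums
#'
#' Closed-form `K x K` window term: given the per-channel helper vectors of
#' one filled window at scale `s` (profile sums, index-weighted sums) and
#' the accumulated outer-product matrix, returns the symmetric matrix whose
#' `(i, j)` entry is the detrended covariance of channels `i` and `j` over
#' that window (normalization `1/s`), with DFA variance terms on the
#' diagonal. Each cross term is symmetrized as \eqn{A + A^T}; elementwise
#' the result equals the pairwise closed form [f2_from_helpers()].
#'
#' @param h list with `sx`, `sxi` (length-`K` vectors) and `sx2`
#'   (`K x K` matrix of summed outer products) over one window.
#' @param s window length.
#' @return Symmetric `K x K` matrix of window detrended covariances.
#' @export
f2_matrix_from_helpers <- function(h, s) {
  m <- -6 * (-2 * h$sxi + (s + 1) * h$sx) / (s * (s^2 - 1))
  b <- h$sx / s - m * (s + 1) / 2
  cc <- s * s / 3 + s / 2 + 1 / 6
  hs <- (s + 1) / 2
  M1 <- m %o% h$sxi
  B1 <- b %o% h$sx
  Mb <- m %o% b
  (h$sx2 - (M1 + t(M1)) - (B1 + t(B1))) / s +
    cc * (m %o% m) + hs * (Mb + t(Mb)) + b %o% b
}

#' Coefficient array and DFA exponents from a scaling-function array
#'
#' Converts an accumulated `K x K x n_s` array of scaling functions
#' \eqn{F^2(i,j,s)} into the detrended cross-correlation coefficient array
#' \eqn{\rho(i,j,s) = F^2(i,j,s) / \sqrt{F^2(i,i,s) F^2(j,j,s)}} and fits
#' each channel's DFA exponent \eqn{\alpha} on the square root of its
#' diagonal. Channels whose diagonal is not strictly positive at every
#' scale (e.g. a constant channel) get `NA` coefficients and exponent;
#' other channels are unaffected.
#'
#' @param F2 numeric array `K x K x n_s`.
#' @param scales a [scale_set()] or numeric vector of `n_s` scales.
#' @param channels optional channel names.
#' @return An object of class `"dcca_multi_estimate"`: list with `F2`,
#'   `rho` (both `K x K x n_s`), `alpha` (length `K`), `scales`,
#'   `channels` and `t` (`NA` when not produced by a stream).
#' @export
dccc_from_f2 <- function(F2, scales, channels = NULL) {
  scl <- if (inherits(scales, "scale_set")) scales$scales else as.numeric(scales)
  d <- dim(F2)
  if (length(d) != 3L || d[1L] != d[2L] || d[3L] != length(scl))
    stopf("F2 must be a K x K x n_s array matching the scales")
  K <- d[1L]
  ns <- d[3L]
  rho <- array(NA_real_, dim = d)
  dg <- matrix(0, K, ns)
  for (q in seq_len(ns)) dg[, q] <- diag(matrix(F2[, , q], K, K))
  ok <- .rowSums(dg > 0, K, ns) == ns
  for (q in seq_len(ns)) {
    dq <- dg[, q]
    den <- sqrt(dq %o% dq)
    r <- matrix(F2[, , q], K, K) / den
    r[!ok, ] <- NA_real_
    r[, !ok] <- NA_real_
    rho[, , q] <- r
  }
  alpha <- rep(NA_real_, K)
  llog <- log(scl)
  for (ch in which(ok)) alpha[ch] <- lsq_slope(llog, log(sqrt(dg[ch, ])))
  structure(list(t = NA_real_, scales = scl, F2 = F2, rho = rho,
                 alpha = alpha, channels = channels %||% paste0("ch", seq_len(K))),
            class = "dcca_multi_estimate")
}

#' @export
print.dcca_multi_estimate <- function(x, ...) {
  K <- dim(x$F2)[1L]
  cat(sprintf("matrix DCCA estimate at t = %g: K = %d channels, %d scales\n",
              x$t, K, length(x$scales)))
  cat("alpha:", paste(sprintf("%s = %.3f", x$channels, x$alpha), collapse = ", "), "\n")
  cat(sprintf("rho at s = %g:\n", x$scales[1L]))
  r <- x$rho[, , 1L]
  dimnames(r) <- list(x$channels, x$channels)
  print(round(r, 3))
  invisible(x)
}
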