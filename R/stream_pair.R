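#' Streaming DCCA engine for a signal pair
#'
#' Creates a one-pass estimator of the DCCA/DFA scaling functions and the
#' detrended cross-correlation coefficient for two simultaneously sampled
#' signals. Samples are fed with [stream_push()]; the engine integrates the
#' pair on the fly and maintains, for every scale `s`, running helper sums
#' of the profile (\eqn{\sum X}, \eqn{\sum iX}, \eqn{\sum XY},
#' \eqn{\sum X^2}, ...) over the currently filling window. When a window at
#' scale `s` fills (every `s` samples) the window's detrended covariance
#' and detrended variances are produced in closed form from the helper sums
#' alone, the sums are reset, and the values are accumulated into the
#' current `s_max`-block. A ring of `W / s_max` block records implements the
#' circular analysis window: the first estimate is emitted once `W` samples
#' have been consumed, then every `s_max` samples, with the oldest block
#' dropped as each new one completes.
#'
#' Memory is a function of the scale set only; the signal itself is never
#' stored.
#'
#' @param scales a [scale_set()] (or numeric scale vector; `W` then
#'   defaults to `4 * s_max`).
#' @return An object of class `"dcca_stream"` (a mutable state handle).
#' @examples
#' st <- dcca_stream(scale_set(8, 64, W = 256))
#' set.seed(1)
#' stream_push(st, rnorm(256), rnorm(256))
#' stream_estimate(st)$rho
#' @seealso [dcca_stream_multi()] for the K-channel matrix engine.
#' @export
dcca_stream <- function(scales = scale_set()) {
  sc <- if (inherits(scales, "scale_set")) scales else
    scale_set(W = 4 * max(scales), scales = scales)
  e <- new.env(parent = emptyenv())
  e$sc <- sc
  s <- sc$scales
  ns <- sc$n_s
  e$t <- 0
  e$X <- 0; e$Y <- 0
  e$sx <- e$sy <- e$sxi <- e$syi <- numeric(ns)
  e$sxy <- e$sx2 <- e$sy2 <- numeric(ns)
  e$blk_xy <- e$blk_xx <- e$blk_yy <- numeric(ns)
  e$ring_xy <- e$ring_xx <- e$ring_yy <- matrix(0, sc$n_blocks, ns)
  e$blocks_seen <- 0
  e$nwin <- numeric(ns)          # completed windows per scale (diagnostics)
  e$last <- NULL
  class(e) <- "dcca_stream"
  e
}

#' @export
print.dcca_stream <- function(x, ...) {
  cat(sprintf("streaming DCCA engine: %d scales %g..%g, W = %g; %g samples seen\n",
              x$sc$n_s, x$sc$s_min, x$sc$s_max, x$sc$W, x$t))
  invisible(x)
}

#' Push samples into a streaming engine
#'
#' Feeds one or more samples, updating every per-scale accumulator and
#' emitting new scaling estimates whenever the analysis window advances.
#' Results are bit-identical whether samples arrive one at a time or in
#' chunks of any size.
#'
#' @param stream a [dcca_stream()] or [dcca_stream_multi()] handle.
#' @param x for the pairwise engine, numeric vector of samples of the first
#'   signal; for the matrix engine, a length-`K` sample vector or an
#'   `n x K` matrix of consecutive samples.
#' @param y pairwise engine only: samples of the second signal, same length
#'   as `x`.
#' @param ... unused.
#' @return Invisibly, the list of estimates emitted while consuming these
#'   samples (empty until `W` samples have been seen). The latest estimate
#'   is also available from [stream_estimate()].
#' @export
stream_push <- function(stream, x, ...) UseMethod("stream_push")

#' @rdname stream_push
#' @export
stream_push.dcca_stream <- function(stream, x, y, ...) {
  n <- length(x)
  if (length(y) != n) stopf("x and y chunks differ in length (%d vs %d)", n, length(y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stopf("non-finite sample at stream index %g", stream$t + bad[1L])
  e <- stream
  sc <- e$sc
  scl <- sc$scales
  smax <- sc$s_max
  nblk <- sc$n_blocks
  W <- sc$W
  emitted <- list()
  for (k in seq_len(n)) {
    e$X <- X <- e$X + x[k]
    e$Y <- Y <- e$Y + y[k]
    t <- e$t <- e$t + 1
    i <- (t - 1) %% scl + 1
    e$sx <- e$sx + X;       e$sy <- e$sy + Y
    e$sxi <- e$sxi + i * X; e$syi <- e$syi + i * Y
    e$sxy <- e$sxy + X * Y
    e$sx2 <- e$sx2 + X * X; e$sy2 <- e$sy2 + Y * Y
    done <- i == scl
    if (any(done)) {
      s <- scl[done]
      mx <- -6 * (-2 * e$sxi[done] + (s + 1) * e$sx[done]) / (s * (s^2 - 1))
      bx <- e$sx[done] / s - mx * (s + 1) / 2
      my <- -6 * (-2 * e$syi[done] + (s + 1) * e$sy[done]) / (s * (s^2 - 1))
      by <- e$sy[done] / s - my * (s + 1) / 2
      cc <- s * s / 3 + s / 2 + 1 / 6
      hs <- (s + 1) / 2
      f2xy <- (e$sxy[done] - (mx * e$syi[done] + my * e$sxi[done]) -
                 (bx * e$sy[done] + by * e$sx[done])) / s +
        cc * (mx * my) + hs * (mx * by + my * bx) + bx * by
      f2xx <- (e$sx2[done] - (mx * e$sxi[done] + mx * e$sxi[done]) -
                 (bx * e$sx[done] + bx * e$sx[done])) / s +
        cc * (mx * mx) + hs * (mx * bx + mx * bx) + bx * bx
      f2yy <- (e$sy2[done] - (my * e$syi[done] + my * e$syi[done]) -
                 (by * e$sy[done] + by * e$sy[done])) / s +
        cc * (my * my) + hs * (my * by + my * by) + by * by
      e$blk_xy[done] <- e$blk_xy[done] + f2xy
      e$blk_xx[done] <- e$blk_xx[done] + f2xx
      e$blk_yy[done] <- e$blk_yy[done] + f2yy
      e$nwin[done] <- e$nwin[done] + 1
      e$sx[done] <- e$sy[done] <- e$sxi[done] <- e$syi[done] <- 0
      e$sxy[done] <- e$sx2[done] <- e$sy2[done] <- 0
    }
    if (t %% smax == 0) {
      pos <- e$blocks_seen %% nblk + 1
      e$ring_xy[pos, ] <- e$blk_xy
      e$ring_xx[pos, ] <- e$blk_xx
      e$ring_yy[pos, ] <- e$blk_yy
      e$blk_xy[] <- e$blk_xx[] <- e$blk_yy[] <- 0
      e$blocks_seen <- e$blocks_seen + 1
      if (t >= W) {
        den <- sc$wins_per_scale
        F2xy <- .colSums(e$ring_xy, nblk, sc$n_s) / den
        F2xx <- .colSums(e$ring_xx, nblk, sc$n_s) / den
        F2yy <- .colSums(e$ring_yy, nblk, sc$n_s) / den
        est <- structure(
          list(t = t, scales = scl,
               F2_xy = F2xy, F2_x = F2xx, F2_y = F2yy,
               rho = F2xy / sqrt(F2xx * F2yy),
               alpha_x = if (all(F2xx > 0)) lsq_slope(log(scl), log(sqrt(F2xx))) else NA_real_,
               alpha_y = if (all(F2yy > 0)) lsq_slope(log(scl), log(sqrt(F2yy))) else NA_real_),
          class = "dcca_estimate")
        e$last <- est
        emitted[[length(emitted) + 1L]] <- est
      }
    }
  }
  invisible(emitted)
}

#' Latest streaming estimate
#'
#' @param stream a streaming engine handle.
#' @return The most recently emitted estimate, or `NULL` while fewer than
#'   `W` samples have been consumed (warm-up).
#' @export
stream_estimate <- function(stream) stream$last

#' Completed-window counts per scale
#'
#' Diagnostic: how many windows have been completed (and folded into block
#' sums) at each scale since the stream started. After exactly `W` samples
#' this equals `W / s` for every scale `s`.
#'
#' @param stream a streaming engine handle.
#' @return Named numeric vector, one count per scale.
#' @export
stream_windows <- function(stream) {
  out <- stream$nwin
  names(out) <- stream$sc$scales
  out
}

#' @export
print.dcca_estimate <- function(x, ...) {
  cat(sprintf("DCCA estimate at t = %g\n", x$t))
  print(data.frame(scale = x$scales, F2_xy = x$F2_xy,
                   F2_x = x$F2_x, F2_y = x$F2_y, rho = x$rho),
        row.names = FALSE)
  cat(sprintf("alpha_x = %.4f, alpha_y = %.4f\n", x$alpha_x, x$alpha_y))
  invisible(x)
}

# ---- helper-variable closed forms (exposed for verification) -------------

#' Linear trend coefficients from helper sums
#'
#' Closed form of the within-window least-squares trend using only the
#' running sums \eqn{\sum X} and \eqn{\sum iX} accumulated over a full
#' window of length `s` (relative index `i = 1..s`):
#' \deqn{m = -6(-2\,sxi + (s+1)\,sx) / (s(s^2-1)), \quad
#'       b = sx/s - m(s+1)/2.}
#'
#' @param sx sum of the profile values over the window.
#' @param sxi index-weighted sum \eqn{\sum_{i=1}^{s} i X(i)}.
#' @param s window length (`s >= 2`).
#' @return A list with slope `m` and intercept `b`, identical (to rounding)
#'   to [ols_trend()] on the same segment.
#' @export
trend_from_helpers <- function(sx, sxi, s) {
  if (s < 2) stopf("window of length %s cannot be detrended", s)
  m <- -6 * (-2 * sxi + (s + 1) * sx) / (s * (s^2 - 1))
  list(m = m, b = sx / s - m * (s + 1) / 2)
}

#' Detrended covariance of a window from helper sums
#'
#' One-pass closed form of the detrended covariance (normalization `1/s`)
#' of a filled window, using only the helper sums of the two profiles; no
#' stored samples are needed. Equals [detrended_cov()] with `norm = "s"` on
#' the same segments up to rounding.
#'
#' @param h list of helper sums over one window of length `s`: `sx`, `sy`
#'   (profile sums), `sxi`, `syi` (index-weighted sums), `sxy`
#'   (cross-product sum).
#' @param s window length.
#' @return Scalar \eqn{f^2_{DCCA}(s)} of the window.
#' @export
f2_from_helpers <- function(h, s) {
  tx <- trend_from_helpers(h$sx, h$sxi, s)
  ty <- trend_from_helpers(h$sy, h$syi, s)
  cc <- s * s / 3 + s / 2 + 1 / 6
  hs <- (s + 1) / 2
  (h$sxy - (tx$m * h$syi + ty$m * h$sxi) - (tx$b * h$sy + ty$b * h$sx)) / s +
    cc * (tx$m * ty$m) + hs * (tx$m * ty$b + ty$m * tx$b) + tx$b * ty$b
}

#' Detrended variance of a window from helper sums
#'
#' Univariate special case of [f2_from_helpers()] (both profiles equal):
#' the window's mean squared detrended residual, i.e. a one-pass DFA window
#' term. Requires the squared-profile sum `sy2` in addition to `sy`, `syi`.
#'
#' @param h list with helper sums `sy`, `syi`, `sy2` over one window.
#' @param s window length.
#' @return Scalar \eqn{f^2_{DFA}(s) \ge 0}.
#' @export
f2_dfa_from_helpers <- function(h, s) {
  tr <- trend_from_helpers(h$sy, h$syi, s)
  cc <- s * s / 3 + s / 2 + 1 / 6
  (h$sy2 - 2 * tr$m * h$syi - 2 * tr$b * h$sy) / s +
    cc * tr$m^2 + tr$m * tr$b * (s + 1) + tr$b^2
}
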