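#' Cumulative integration of a time series
#'
#' Both DFA and DCCA operate on the integrated signal (the "profile"), i.e.
#' the running sum \eqn{X(t) = \sum_{i \le t} x(i)}, which turns a
#' stationary increment process into a random-walk-like profile whose
#' detrended fluctuations carry the scaling information.
#'
#' @param x numeric vector of at least two finite samples.
#' @return Numeric vector of the same length: the cumulative sum.
#' @examples
#' integrate_series(c(1, 1, 1, 1))  # 1 2 3 4
#' @export
integrate_series <- function(x) {
  if (length(x) < 2L) stopf("series must have at least 2 samples")
  check_finite_series(x)
  cumsum(x)
}

#' Least-squares linear trend of a window
#'
#' Fits `segment[i] = m * i + b` by ordinary least squares against the
#' relative (1-based) within-window index `i = 1..s`. This is the local
#' trend removed from each window of the integrated profile.
#'
#' @param segment numeric vector of length `s >= 2`.
#' @return A list with elements `m` (slope per sample) and `b` (intercept).
#' @examples
#' ols_trend(2 * (1:8) + 1)  # m = 2, b = 1
#' @export
ols_trend <- function(segment) {
  s <- length(segment)
  if (s < 2L) stopf("window of length %d cannot be detrended", s)
  i <- seq_len(s)
  Si <- s * (s + 1) / 2
  den <- s * (s * (s + 1) * (2 * s + 1) / 6) - Si^2
  m <- (s * sum(i * segment) - Si * sum(segment)) / den
  b <- (sum(segment) - m * Si) / s
  list(m = m, b = b)
}

#' Detrended covariance of one window pair
#'
#' Removes each segment's own least-squares linear trend and returns the
#' normalized sum of residual products. With `Xseg == Yseg` this is the
#' detrended variance (a DFA window term) and is non-negative; for distinct
#' segments it may take either sign.
#'
#' @param Xseg,Yseg integrated-profile segments of equal length `s >= 3`.
#' @param norm `"s"` divides the residual products by the window length
#'   (matching the streaming formulas); `"s-1"` gives the unbiased-covariance
#'   flavour used by the classical sliding-window formulation.
#' @return Scalar detrended covariance of the window.
#' @export
detrended_cov <- function(Xseg, Yseg, norm = c("s", "s-1")) {
  norm <- match.arg(norm)
  s <- length(Xseg)
  if (length(Yseg) != s) stopf("segments differ in length (%d vs %d)", s, length(Yseg))
  if (s < 3L) stopf("window of length %d is too short for detrended covariance", s)
  tx <- ols_trend(Xseg)
  ty <- ols_trend(Yseg)
  i <- seq_len(s)
  rx <- Xseg - tx$m * i - tx$b
  ry <- Yseg - ty$m * i - ty$b
  sum(rx * ry) / if (norm == "s") s else s - 1
}

# Residual matrix of the blocked decomposition at one scale: column j holds
# the detrended residuals of window j. `X` is an integrated profile.
blocked_residuals <- function(X, s) {
  nw <- length(X) %/% s
  M <- matrix(X[seq_len(nw * s)], nrow = s)
  i <- seq_len(s)
  Si <- s * (s + 1) / 2
  den <- s * (s * (s + 1) * (2 * s + 1) / 6) - Si^2
  cs <- .colSums(M, s, nw)
  ci <- as.numeric(crossprod(i, M))
  m <- (s * ci - Si * cs) / den
  b <- (cs - m * Si) / s
  M - outer(i, m) - rep(b, each = s)
}

# Per-scale blocked scaling functions for a pair, sharing the residual
# matrices across the xy/xx/yy combinations. Returns a list of three
# vectors over scales.
blocked_f2_all <- function(X, Y, scales, norm = "s") {
  ns <- length(scales)
  xy <- xx <- yy <- numeric(ns)
  for (q in seq_len(ns)) {
    s <- scales[q]
    rx <- blocked_residuals(X, s)
    ry <- blocked_residuals(Y, s)
    d <- if (norm == "s") s else s - 1
    xy[q] <- mean(.colSums(rx * ry, nrow(rx), ncol(rx))) / d
    xx[q] <- mean(.colSums(rx * rx, nrow(rx), ncol(rx))) / d
    yy[q] <- mean(.colSums(ry * ry, nrow(ry), ncol(ry))) / d
  }
  list(xy = xy, xx = xx, yy = yy)
}

#' Sliding-window DCCA scaling function at one scale
#'
#' The classical formulation: the integrated profiles are divided into all
#' `N - s + 1` overlapping windows of length `s`, each window pair is
#' detrended and its residual covariance computed, and the results are
#' averaged. With `x == y` this reduces to the (squared) DFA fluctuation
#' function.
#'
#' @param x,y numeric time series (raw samples, not profiles) of equal
#'   length `N >= s`.
#' @param s window size.
#' @param norm residual-product normalization, see [detrended_cov()];
#'   defaults to `"s-1"` as in the sliding-window literature.
#' @return Scalar \eqn{F^2(s)}.
#' @export
dcca_sliding <- function(x, y, s, norm = c("s-1", "s")) {
  norm <- match.arg(norm)
  N <- length(x)
  if (length(y) != N) stopf("series differ in length")
  if (s > N) stopf("scale s = %s exceeds series length %d", s, N)
  X <- integrate_series(x)
  Y <- integrate_series(y)
  k <- N - s + 1
  acc <- 0
  for (j in seq_len(k)) {
    idx <- j:(j + s - 1)
    acc <- acc + detrended_cov(X[idx], Y[idx], norm = norm)
  }
  acc / k
}

#' Blocked (non-overlapping) DCCA scaling function
#'
#' Divides the integrated profiles into `floor(N / s)` consecutive
#' non-overlapping windows at each scale, detrends each window and averages
#' the residual covariances. This is the variant the streaming engines
#' reproduce exactly (with `norm = "s"`), and the usual choice with dyadic
#' scales.
#'
#' @inheritParams dcca_sliding
#' @param scales a [scale_set()] or numeric vector of scales with
#'   `max(scales) <= N`.
#' @param norm residual-product normalization, default `"s"` (the streaming
#'   convention).
#' @return Numeric vector of \eqn{F^2_{DCCA}(s)}, one value per scale
#'   (named by scale).
#' @examples
#' set.seed(1)
#' x <- rnorm(256)
#' dcca_blocked(x, x, c(8, 16, 32))  # = squared DFA fluctuation functions
#' @export
dcca_blocked <- function(x, y, scales, norm = c("s", "s-1")) {
  norm <- match.arg(norm)
  sc <- as_scale_set(scales)
  N <- length(x)
  if (length(y) != N) stopf("series differ in length")
  if (sc$s_max > N) stopf("largest scale %s exceeds series length %d", sc$s_max, N)
  X <- integrate_series(x)
  Y <- integrate_series(y)
  ns <- sc$n_s
  out <- numeric(ns)
  for (q in seq_len(ns)) {
    s <- sc$scales[q]
    rx <- blocked_residuals(X, s)
    ry <- blocked_residuals(Y, s)
    d <- if (norm == "s") s else s - 1
    out[q] <- mean(.colSums(rx * ry, nrow(rx), ncol(rx))) / d
  }
  names(out) <- sc$scales
  out
}

#' Blocked DFA scaling function
#'
#' Univariate special case of [dcca_blocked()]: the detrended variance of a
#' single series' profile, per scale. Values are non-negative; their square
#' root is the DFA fluctuation function \eqn{F_{DFA}(s)}.
#'
#' @inheritParams dcca_blocked
#' @param x numeric time series.
#' @return Numeric vector of \eqn{F^2_{DFA}(s)} per scale.
#' @export
dfa_blocked <- function(x, scales, norm = c("s", "s-1")) {
  dcca_blocked(x, x, scales, norm = match.arg(norm))
}

#' Detrended cross-correlation coefficient (DCCC)
#'
#' Normalizes the detrended covariance by the two univariate DFA
#' fluctuation functions,
#' \deqn{\rho_{DCCA}(s) = F^2_{DCCA}(s) / (F_{DFA,x}(s)\, F_{DFA,y}(s)),}
#' the nonstationary analogue of Pearson's r, bounded in \eqn{[-1, 1]}.
#'
#' @inheritParams dcca_blocked
#' @param variant `"blocked"` (non-overlapping windows, default) or
#'   `"sliding"` (all overlapping windows).
#' @return Named numeric vector \eqn{\rho_{DCCA}(s)}, one entry per scale.
#' @examples
#' set.seed(1)
#' x <- rnorm(512)
#' dccc(x, -x, c(8, 16, 32))  # exactly -1 at every scale
#' @export
dccc <- function(x, y, scales, variant = c("blocked", "sliding"),
                 norm = c("s", "s-1")) {
  variant <- match.arg(variant)
  norm <- match.arg(norm)
  sc <- as_scale_set(scales)
  if (variant == "blocked") {
    f <- blocked_f2_all(integrate_series(x), integrate_series(y),
                        sc$scales, norm = norm)
  } else {
    nrm <- if (norm == "s") "s" else "s-1"
    f <- list(
      xy = vapply(sc$scales, function(s) dcca_sliding(x, y, s, norm = nrm), 0),
      xx = vapply(sc$scales, function(s) dcca_sliding(x, x, s, norm = nrm), 0),
      yy = vapply(sc$scales, function(s) dcca_sliding(y, y, s, norm = nrm), 0))
  }
  bad <- f$xx <= 0 | f$yy <= 0
  if (any(bad))
    stopf("DCCC undefined: zero detrended variance at scale %s (constant series?)",
          sc$scales[which(bad)[1L]])
  rho <- f$xy / sqrt(f$xx * f$yy)
  names(rho) <- sc$scales
  rho
}

#' Batch DCCA summary for a signal pair
#'
#' Convenience wrapper computing, per scale, the cross scaling function
#' \eqn{F^2_{DCCA}(s)}, both univariate DFA scaling functions and the
#' coefficient \eqn{\rho_{DCCA}(s)}, plus fitted exponents: the per-channel
#' DFA exponents \eqn{\alpha} and, offline only, the bivariate exponent
#' \eqn{\lambda} fitted on \eqn{|F^2_{DCCA}|^{1/2}} (with a warning when any
#' cross term is non-positive).
#'
#' @inheritParams dccc
#' @return A data frame with columns `scale`, `F2_xy`, `F2_x`, `F2_y`,
#'   `rho`, carrying attributes `alpha_x`, `alpha_y` and `lambda`.
#' @export
dcca <- function(x, y, scales, norm = c("s", "s-1")) {
  norm <- match.arg(norm)
  sc <- as_scale_set(scales)
  f <- blocked_f2_all(integrate_series(x), integrate_series(y),
                      sc$scales, norm = norm)
  rho <- f$xy / sqrt(f$xx * f$yy)
  out <- data.frame(scale = sc$scales, F2_xy = f$xy,
                    F2_x = f$xx, F2_y = f$yy, rho = rho)
  attr(out, "alpha_x") <- fit_exponent(sc$scales, sqrt(f$xx))
  attr(out, "alpha_y") <- fit_exponent(sc$scales, sqrt(f$yy))
  if (any(f$xy <= 0)) {
    warning("non-positive F2_xy at some scale; lambda fitted on |F2|^(1/2)")
  }
  attr(out, "lambda") <- fit_exponent(sc$scales, sqrt(abs(f$xy)))
  out
}

#' Fit a scaling exponent by log-log regression
#'
#' Regresses `log(F)` on `log(s)` by least squares and returns the slope:
#' the DFA exponent \eqn{\alpha} when `F` is a DFA fluctuation function, or
#' the bivariate exponent \eqn{\lambda} when `F` is the (positive) square
#' root of the cross scaling function. Natural logarithms are used; the
#' slope is base-invariant.
#'
#' @param scales a [scale_set()] or numeric vector of scales.
#' @param F positive per-scale fluctuation values, same length as the
#'   scales.
#' @return Scalar slope.
#' @examples
#' s <- 2^(3:7)
#' fit_exponent(s, s^0.8)  # 0.8
#' @export
fit_exponent <- function(scales, F) {
  sc <- if (inherits(scales, "scale_set")) scales$scales else as.numeric(scales)
  if (length(F) != length(sc)) stopf("F and scales differ in length")
  bad <- which(!(F > 0))
  if (length(bad))
    stopf("cannot fit exponent: non-positive value at scale %s", sc[bad[1L]])
  lsq_slope(log(sc), log(F))
}
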