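#' ARFIMA autoregressive weights
#'
#' Weights of the AR(\eqn{\infty}) representation of a fractionally
#' integrated process with memory parameter `d`:
#' \deqn{a_n(d) = d\,\Gamma(n - d) / (\Gamma(1 - d)\,\Gamma(n + 1)),}
#' evaluated through log-gamma so large lags do not overflow. The weights
#' decay as \eqn{n^{d-1}}; `d = 0` gives all-zero weights (pure noise).
#'
#' @param d memory parameter, `0 <= d < 0.5`.
#' @param n_max number of lags.
#' @return Numeric vector `a_1..a_n_max`; note `a_1 = d` for any `d`.
#' @examples
#' arfima_weights(0.3, 5)
#' @export
arfima_weights <- function(d, n_max) {
  if (length(d) != 1L || !is.finite(d) || d < 0 || d >= 0.5)
    stopf("memory parameter d must lie in [0, 0.5) (got %s)", d)
  if (n_max < 1) stopf("n_max must be at least 1")
  if (d == 0) return(numeric(n_max))
  n <- seq_len(n_max)
  exp(log(d) + lgamma(n - d) - lgamma(1 - d) - lgamma(n + 1))
}

# Core recursion x_t = sum_n a_n(d) x_{t-n} + eps_t, truncated at n_trunc,
# driven by a given innovation vector. Zero initial conditions.
arfima_filter <- function(eps, d, n_trunc) {
  if (d == 0) return(eps)
  as.numeric(stats::filter(eps, arfima_weights(d, n_trunc),
                           method = "recursive"))
}

#' Simulate a single ARFIMA(d) long-memory process
#'
#' Generates the truncated recursion
#' \eqn{x_t = \sum_{n=1}^{n_{trunc}} a_n(d) x_{t-n} + \epsilon_t} with
#' i.i.d. standard normal innovations, discarding an initial burn-in so the
#' retained stretch is free of the zero initial condition. The process has
#' long-range autocorrelations with DFA exponent \eqn{\alpha = 0.5 + d};
#' `d = 0` is white noise.
#'
#' @param N retained series length (`N >= 64`).
#' @param d memory parameter in `[0, 0.5)`.
#' @param seed optional integer for reproducibility (the caller's RNG
#'   stream is left untouched).
#' @param n_trunc truncation lag of the infinite sum; default
#'   `min(N, 1000)`. The weights decay as \eqn{n^{d-1}}, so this bounds the
#'   neglected tail.
#' @param burn_in samples discarded from the start; default `n_trunc`.
#' @param innovations optional vector of `N + burn_in` innovations driving
#'   the recursion (overrides `seed`), e.g. correlated ones.
#' @return Numeric vector of length `N`.
#' @examples
#' x <- simulate_arfima(512, d = 0.3, seed = 1)
#' @export
simulate_arfima <- function(N, d = 0.3, seed = NULL,
                            n_trunc = min(N, 1000), burn_in = n_trunc,
                            innovations = NULL) {
  if (N < 64) stopf("N must be at least 64 (got %s)", N)
  M <- N + burn_in
  eps <- if (is.null(innovations)) with_seed(seed, stats::rnorm(M)) else {
    if (length(innovations) != M)
      stopf("innovations must have length N + burn_in = %d", M)
    innovations
  }
  x <- arfima_filter(eps, d, n_trunc)
  x[(burn_in + 1):M]
}

#' Parameters of the mixed-correlated ARFIMA pair
#'
#' The generator builds two observed series, each a weighted sum of two
#' independent ARFIMA components,
#' \deqn{x_t = w_1\,c_1(d_1) + w_2\,c_2(d_2), \qquad
#'       y_t = w_3\,c_3(d_3) + w_4\,c_4(d_4),}
#' whose innovation 4-vectors are jointly Gaussian with unit variances
#' (configurable) and correlation matrix `rho`. Long-range
#' cross-correlation between x and y is induced by correlating the
#' innovations of components 2 and 3 (`rho23`), giving a bivariate scaling
#' exponent \eqn{\lambda = (d_2 + d_3 + 1)/2}.
#'
#' The defaults reproduce the strongly cross-persistent setting used for
#' the simulation experiments: `w1 = w4 = 0.2`, `w2 = w3 = 1`,
#' `d1 = d4 = 0.4`, `d2 = d3 = 0.3`, unit innovation variances and
#' `rho23 = 0.9` (all other correlations zero).
#'
#' @param w1,w2,w3,w4 component weights.
#' @param d1,d2,d3,d4 memory parameters in `[0, 0.5)` (0 admits the
#'   white-noise limit).
#' @param sigma2 length-4 innovation variances.
#' @param rho23 innovation correlation of components 2 and 3; ignored when
#'   a full `rho` matrix is given.
#' @param rho optional full 4 x 4 innovation correlation matrix (unit
#'   diagonal, symmetric, positive semi-definite).
#' @param n_trunc,burn_in recursion truncation and discarded warm-up; `NULL`
#'   defers to the series length at simulation time (`min(N, 1000)`).
#' @return An object of class `"mc_arfima_params"`.
#' @export
mc_arfima_params <- function(w1 = 0.2, w2 = 1, w3 = 1, w4 = 0.2,
                             d1 = 0.4, d2 = 0.3, d3 = 0.3, d4 = 0.4,
                             sigma2 = rep(1, 4), rho23 = 0.9, rho = NULL,
                             n_trunc = NULL, burn_in = NULL) {
  d <- c(d1, d2, d3, d4)
  if (any(!is.finite(d) | d < 0 | d >= 0.5))
    stopf("memory parameters must lie in [0, 0.5)")
  if (length(sigma2) != 4L || any(sigma2 <= 0))
    stopf("sigma2 must be 4 positive innovation variances")
  if (is.null(rho)) {
    rho <- diag(4)
    rho[2, 3] <- rho[3, 2] <- rho23
  }
  if (!isTRUE(all.equal(rho, t(rho))) || any(diag(rho) != 1))
    stopf("rho must be symmetric with unit diagonal")
  Sigma <- rho * sqrt(sigma2 %o% sigma2)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev)))
    stopf("innovation covariance is not positive semi-definite")
  structure(list(w = c(w1, w2, w3, w4), d = d, sigma2 = sigma2,
                 rho = rho, Sigma = Sigma,
                 n_trunc = n_trunc, burn_in = burn_in),
            class = "mc_arfima_params")
}

#' @export
print.mc_arfima_params <- function(x, ...) {
  cat("mc-ARFIMA parameters\n")
  cat("  weights: ", paste(x$w, collapse = ", "), "\n")
  cat("  memory d:", paste(x$d, collapse = ", "), "\n")
  cat("  innovation correlations (off-diagonal nonzero):",
      sprintf("rho[2,3] = %g", x$rho[2, 3]), "\n")
  invisible(x)
}

#' Simulate a mixed-correlated ARFIMA pair
#'
#' Draws the four innovation streams as correlated Gaussian 4-vectors
#' (Cholesky factor of the innovation covariance; correlation only at lag
#' zero), runs the four ARFIMA recursions and mixes them into the observed
#' pair. See [mc_arfima_params()] for the model and defaults.
#'
#' @param N retained series length.
#' @param params an [mc_arfima_params()] object.
#' @param seed optional integer seed (caller's RNG untouched).
#' @param innovations optional `(N + burn_in) x 4` matrix of *uncorrelated*
#'   standard innovations to be mixed by the Cholesky factor; overrides
#'   `seed`.
#' @return List with numeric vectors `x` and `y` of length `N`.
#' @examples
#' p <- simulate_mc_arfima(512, seed = 7)
#' dccc(p$x, p$y, c(8, 16, 32, 64))
#' @export
simulate_mc_arfima <- function(N, params = mc_arfima_params(), seed = NULL,
                               innovations = NULL) {
  stopifnot(inherits(params, "mc_arfima_params"))
  n_trunc <- params$n_trunc %||% min(N, 1000)
  burn_in <- params$burn_in %||% n_trunc
  M <- N + burn_in
  Z <- if (is.null(innovations)) {
    with_seed(seed, matrix(stats::rnorm(4 * M), M, 4))
  } else {
    if (!is.matrix(innovations) || nrow(innovations) != M || ncol(innovations) != 4L)
      stopf("innovations must be a (N + burn_in) x 4 matrix")
    innovations
  }
  eps <- Z %*% chol(params$Sigma)
  comp <- matrix(0, N, 4)
  keep <- (burn_in + 1):M
  for (j in 1:4)
    comp[, j] <- arfima_filter(eps[, j], params$d[j], n_trunc)[keep]
  list(x = params$w[1] * comp[, 1] + params$w[2] * comp[, 2],
       y = params$w[3] * comp[, 3] + params$w[4] * comp[, 4])
}

#' Contaminate a series with additive white noise at a given SNR
#'
#' Adds i.i.d. Gaussian noise with variance `var(x) / snr`, where the
#' signal-to-noise ratio is the ratio of the variance of the original
#' signal to the variance of the added component.
#'
#' @param x numeric series (non-constant).
#' @param snr positive signal-to-noise ratio (variance ratio).
#' @param seed optional integer seed.
#' @return Contaminated series of the same length.
#' @export
add_white_noise <- function(x, snr, seed = NULL) {
  if (snr <= 0) stopf("snr must be positive")
  v <- stats::var(x)
  if (v == 0) stopf("SNR is undefined for a constant series")
  x + with_seed(seed, stats::rnorm(length(x), 0, sqrt(v / snr)))
}

#' Specification of Hanning spike artifacts
#'
#' Transient artifacts are modelled as raised-cosine (Hanning) bumps of
#' fixed width, placed uniformly at random without overlap, with peak
#' height `amplitude` times the variance (default) or standard deviation
#' of the host series. Contamination types: `"A"` adds spikes to the first
#' series only; `"B"` adds independently placed spikes to both; `"C"` adds
#' spikes at identical positions to both.
#'
#' @param count number of spikes (default 10).
#' @param width spike width in samples (default 20).
#' @param amplitude peak height factor (default 4).
#' @param type `"A"`, `"B"` or `"C"`.
#' @param units `"variance"` (default, peak = amplitude x var(host)) or
#'   `"sd"` (peak = amplitude x sd(host)).
#' @return An object of class `"spike_spec"`.
#' @export
spike_spec <- function(count = 10, width = 20, amplitude = 4,
                       type = c("A", "B", "C"),
                       units = c("variance", "sd")) {
  type <- match.arg(type)
  units <- match.arg(units)
  if (count < 1 || width < 3) stopf("need count >= 1 and width >= 3")
  structure(list(count = count, width = width, amplitude = amplitude,
                 type = type, units = units),
            class = "spike_spec")
}

# Non-overlapping uniform placement by rejection sampling.
place_spikes <- function(N, count, width, max_tries = 10000L) {
  if (N < count * width)
    stopf("cannot place %d non-overlapping spikes of width %d in %d samples",
          count, width, N)
  pos <- integer(0)
  tries <- 0L
  while (length(pos) < count) {
    p <- sample.int(N - width + 1L, 1L)
    if (!any(abs(p - pos) < width)) pos <- c(pos, p)
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("failed to place %d non-overlapping spikes of width %d in %d samples",
            count, width, N)
  }
  sort(pos)
}

hanning_bump <- function(width) {
  k <- seq_len(width) - 1L
  0.5 * (1 - cos(2 * pi * k / (width - 1)))
}

add_bumps <- function(x, pos, width, peak) {
  h <- hanning_bump(width) * peak
  for (p in pos) {
    idx <- p:(p + width - 1L)
    x[idx] <- x[idx] + h
  }
  x
}

#' Add Hanning spike artifacts to a signal pair
#'
#' Applies the contamination described by a [spike_spec()] to the pair.
#' Peak height is scaled per host series (`amplitude` times its variance
#' by default), so for Type C the two series receive bumps at identical
#' positions, identical in shape and equal in height exactly when the host
#' variances are equal.
#'
#' @param x,y numeric series of equal length `N >= count * width`.
#' @param spec a [spike_spec()].
#' @param seed optional integer seed controlling placement.
#' @return List with contaminated `x`, `y` and the placement vectors
#'   `positions_x`, `positions_y` (`NULL` where no spikes were added).
#' @examples
#' set.seed(1)
#' x <- rnorm(512); y <- rnorm(512)
#' out <- add_spikes(x, y, spike_spec(type = "A"), seed = 2)
#' identical(out$y, y)  # TRUE: Type A leaves y unchanged
#' @export
add_spikes <- function(x, y, spec = spike_spec(), seed = NULL) {
  stopifnot(inherits(spec, "spike_spec"))
  N <- length(x)
  if (length(y) != N) stopf("series differ in length")
  scale_of <- function(z)
    if (spec$units == "variance") stats::var(z) else stats::sd(z)
  with_seed(seed, {
    px <- place_spikes(N, spec$count, spec$width)
    py <- switch(spec$type,
                 A = NULL,
                 B = place_spikes(N, spec$count, spec$width),
                 C = px)
    xo <- add_bumps(x, px, spec$width, spec$amplitude * scale_of(x))
    yo <- if (is.null(py)) y else
      add_bumps(y, py, spec$width, spec$amplitude * scale_of(y))
    list(x = xo, y = yo, positions_x = px, positions_y = py)
  })
}
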