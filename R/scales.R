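#' Analysis scales and streaming window configuration
#'
#' A scale set collects the window sizes (scales) `s` at which detrended
#' fluctuation and covariance are measured, together with the length `W` of
#' the circular analysis window used by the streaming engines. Scales are
#' dyadic by default (powers of two), which samples the log-log scaling plot
#' evenly. The streaming engines advance their analysis window in steps of
#' the largest scale, so `W` must be an integer multiple of `s_max` and every
#' scale must divide `s_max`.
#'
#' The defaults mirror a 256 Hz EEG setting: scales \eqn{2^3}--\eqn{2^7} in a
#' `W = 512`-sample (2 s) window, so a new estimate is emitted every 2 s.
#'
#' @param s_min,s_max smallest and largest scale, in samples. Both must be
#'   powers of two with `s_min >= 4`.
#' @param W analysis-window length in samples; a multiple of `s_max`.
#' @param scales optional explicit vector of scales overriding the dyadic
#'   range; must be strictly increasing divisors of `s_max`.
#' @return An object of class `"scale_set"`: a list with elements `scales`,
#'   `n_s`, `s_min`, `s_max`, `W`, `n_blocks` (= `W / s_max`) and
#'   `wins_per_scale` (= `W / s`, the number of windows of each scale
#'   averaged into one estimate).
#' @examples
#' scale_set()                      # EEG default: 8..128 in W = 512
#' scale_set(4, 256, W = 1024)     # W = N preset for a 2^10-sample batch
#' @seealso [dyadic_preset()] for length-indexed presets.
#' @export
scale_set <- function(s_min = 8, s_max = 128, W = 4L * s_max, scales = NULL) {
  if (is.null(scales)) {
    if (!is_pow2(s_min) || !is_pow2(s_max))
      stopf("s_min and s_max must be powers of two (got %s, %s)", s_min, s_max)
    scales <- 2^(log2(s_min):log2(s_max))
  }
  scales <- as.numeric(scales)
  if (length(scales) < 1L || any(diff(scales) <= 0))
    stopf("scales must be strictly increasing")
  s_min <- scales[1L]
  s_max <- scales[length(scales)]
  if (s_min < 4) stopf("smallest scale must be at least 4 samples (got %s)", s_min)
  if (any(s_max %% scales != 0))
    stopf("every scale must divide s_max = %s", s_max)
  if (W < s_max) stopf("analysis window W = %s is smaller than s_max = %s", W, s_max)
  if (W %% s_max != 0)
    stopf("analysis window W = %s must be a multiple of s_max = %s", W, s_max)
  structure(
    list(scales = scales, n_s = length(scales),
         s_min = s_min, s_max = s_max, W = as.numeric(W),
         n_blocks = as.integer(W / s_max),
         wins_per_scale = as.numeric(W) / scales),
    class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf("scale set: %d dyadic scales %g..%g, analysis window W = %g (%d blocks of s_max)\n",
              x$n_s, x$s_min, x$s_max, x$W, x$n_blocks))
  invisible(x)
}

# (s_min, s_max) exponents per signal length used throughout the runtime and
# precision experiments; W defaults to the batch length.
.preset_table <- list(
  `8`  = c(2, 6),  `9`  = c(2, 7),  `10` = c(2, 8),  `11` = c(3, 9),
  `12` = c(3, 10), `13` = c(3, 10), `14` = c(4, 11), `15` = c(4, 11),
  `16` = c(4, 12), `17` = c(4, 12))

#' Dyadic scale presets indexed by signal length
#'
#' Returns the scale set conventionally paired with a batch of `N = 2^8` ..
#' `2^17` samples: the scale range widens with the signal so that `s_max`
#' stays a small fraction of `N`, keeping enough windows per scale for a
#' stable average.
#'
#' @param N signal (and default analysis-window) length; a power of two
#'   between `2^8` and `2^17`.
#' @param W analysis-window length, defaulting to `N` so a batch yields one
#'   estimate.
#' @return A [scale_set()].
#' @examples
#' dyadic_preset(1024)  # scales 2^2..2^8
#' @export
dyadic_preset <- function(N, W = N) {
  if (!is_pow2(N)) stopf("preset lengths are powers of two (got %s)", N)
  key <- as.character(log2(N))
  e <- .preset_table[[key]]
  if (is.null(e))
    stopf("no preset for N = %s; presets cover 2^8..2^17", N)
  scale_set(2^e[1L], 2^e[2L], W = W)
}

as_scale_set <- function(scales, W = NULL) {
  if (inherits(scales, "scale_set")) return(scales)
  s <- as.numeric(scales)
  scale_set(W = if (is.null(W)) max(s) else W, scales = s)
}
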