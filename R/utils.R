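# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

is_pow2 <- function(x) {
  x == round(x) & x >= 1 & bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# Closed-form OLS slope of f on l; algebraically what lm() returns.
lsq_slope <- function(l, f) {
  lc <- l - mean(l)
  sum(lc * (f - mean(f))) / sum(lc * lc)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_finite_series <- function(x, name = "x") {
  bad <- which(!is.finite(x))
  if (length(bad))
    stopf("non-finite value in '%s' at index %d", name, bad[1L])
  invisible(x)
}
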