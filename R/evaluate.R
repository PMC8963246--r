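#' Mean squared error between two per-scale coefficient curves
#'
#' \eqn{MSE = n_s^{-1} \sum_s (\rho_a(s) - \rho_b(s))^2}, the summary used
#' throughout the precision and robustness experiments.
#'
#' @param rho_a,rho_b numeric vectors of equal length (one value per
#'   analysis scale).
#' @return Scalar MSE.
#' @export
mse_scales <- function(rho_a, rho_b) {
  if (length(rho_a) != length(rho_b))
    stopf("coefficient curves differ in length (%d vs %d)",
          length(rho_a), length(rho_b))
  mean((rho_a - rho_b)^2)
}

# One streaming pairwise analysis of a whole batch with W = N; returns the
# estimate emitted when the analysis window first fills (= the full batch).
stream_rho_batch <- function(x, y, sc) {
  st <- dcca_stream(sc)
  stream_push(st, x, y)
  est <- stream_estimate(st)
  if (is.null(est)) stopf("batch shorter than the analysis window")
  est
}

stream_rho_batch_multi <- function(x, y, sc) {
  st <- dcca_stream_multi(2L, sc)
  stream_push(st, cbind(x, y))
  est <- stream_estimate(st)
  if (is.null(est)) stopf("batch shorter than the analysis window")
  est
}

#' Streaming-versus-offline precision grid
#'
#' Measures how closely the one-pass engines reproduce the two-pass
#' offline coefficient: mc-ARFIMA pairs are generated over a grid of
#' cross-memory parameters (`d2`, `d3`), each batch is analysed offline
#' (blocked windows, `1/s` normalization, so the comparison isolates the
#' streaming arithmetic) and by a streaming engine with `W = N`, and the
#' per-cell [mse_scales()] between the two coefficient curves is averaged
#' over replicates. The persistent nuisance components are fixed at
#' `d1 = d4 = 0.45`.
#'
#' @param N batch length (a preset power of two); also the analysis window.
#' @param scales a [scale_set()]; defaults to [dyadic_preset()] at `N`.
#' @param d_grid grid values for `d2` and `d3`.
#' @param replicates mc-ARFIMA pairs per cell.
#' @param seed integer seed making the whole grid reproducible.
#' @param engine `"pairwise"` or `"matrix"` streaming implementation.
#' @return Data frame with columns `d2`, `d3`, `condition`, `mse`.
#' @export
precision_experiment <- function(N = 1024, scales = dyadic_preset(N),
                                 d_grid = seq(0.05, 0.45, by = 0.05),
                                 replicates = 10, seed = NULL,
                                 engine = c("pairwise", "matrix")) {
  engine <- match.arg(engine)
  sc <- scales
  grid <- expand.grid(d2 = d_grid, d3 = d_grid)
  with_seed(seed, {
    grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
      pars <- mc_arfima_params(d1 = 0.45, d2 = grid$d2[g],
                               d3 = grid$d3[g], d4 = 0.45)
      mean(vapply(seq_len(replicates), function(r) {
        p <- simulate_mc_arfima(N, pars)
        off <- dccc(p$x, p$y, sc)
        on <- if (engine == "pairwise") stream_rho_batch(p$x, p$y, sc)$rho
              else stream_rho_batch_multi(p$x, p$y, sc)$rho[1, 2, ]
        mse_scales(off, on)
      }, 0))
    }, 0)
    grid$condition <- paste0("offline_vs_online_", engine)
    grid[, c("d2", "d3", "condition", "mse")]
  })
}

#' Robustness of the coefficient to contamination
#'
#' Generates mc-ARFIMA pairs over the (`d2`, `d3`) grid, contaminates each
#' pair with additive white noise at a given SNR or with Hanning spike
#' artifacts (Type A: first series only; B: independent in both; C:
#' identical in both), and reports the per-cell mean over replicates of the
#' [mse_scales()] between the coefficient curves of the clean and
#' contaminated versions of the same pair. The coefficient is computed with
#' the blocked offline implementation, which the streaming engines match to
#' well below the contamination effects being measured.
#'
#' @param kind `"white"`, `"spikeA"`, `"spikeB"` or `"spikeC"`.
#' @param level SNR (variance ratio) for `kind = "white"`; ignored for
#'   spikes.
#' @param N batch length; default `4096`.
#' @param scales a [scale_set()]; defaults to the `N`-indexed preset.
#' @param d_grid grid values for `d2` and `d3`.
#' @param replicates pairs per cell.
#' @param seed integer seed for the whole grid.
#' @param spike a [spike_spec()] template for the spike kinds (its `type`
#'   is taken from `kind`).
#' @return Data frame with columns `d2`, `d3`, `condition`, `mse`.
#' @export
noise_experiment <- function(kind = c("white", "spikeA", "spikeB", "spikeC"),
                             level = 10, N = 4096,
                             scales = dyadic_preset(N),
                             d_grid = seq(0.05, 0.45, by = 0.05),
                             replicates = 10, seed = NULL,
                             spike = spike_spec()) {
  kind <- match.arg(kind)
  sc <- scales
  if (kind != "white")
    spike <- spike_spec(count = spike$count, width = spike$width,
                        amplitude = spike$amplitude,
                        type = sub("spike", "", kind), units = spike$units)
  condition <- if (kind == "white") sprintf("white_snr%g", level) else kind
  grid <- expand.grid(d2 = d_grid, d3 = d_grid)
  with_seed(seed, {
    grid$mse <- vapply(seq_len(nrow(grid)), function(g) {
      pars <- mc_arfima_params(d2 = grid$d2[g], d3 = grid$d3[g])
      mean(vapply(seq_len(replicates), function(r) {
        p <- simulate_mc_arfima(N, pars)
        clean <- dccc(p$x, p$y, sc)
        cont <- if (kind == "white") {
          list(x = add_white_noise(p$x, level),
               y = add_white_noise(p$y, level))
        } else {
          add_spikes(p$x, p$y, spike)
        }
        mse_scales(clean, dccc(cont$x, cont$y, sc))
      }, 0))
    }, 0)
    grid$condition <- condition
    grid[, c("d2", "d3", "condition", "mse")]
  })
}

#' Execution-time scaling of the engines
#'
#' Times whole-batch analyses to characterize how cost grows with batch
#' length (streaming pairwise engine, expected linear in `N`) and with the
#' number of channels (sequential pairwise over all channel pairs versus
#' the matrix engine). Only relative growth is meaningful; absolute
#' seconds depend on the host.
#'
#' @param N batch lengths to time (preset powers of two).
#' @param K channel counts for the pairwise-versus-matrix comparison;
#'   `NULL` skips it.
#' @param N_multi batch length used in the channel-count comparison.
#' @param replicates timed repetitions per configuration (median reported).
#' @param seed integer seed for the simulated inputs.
#' @return Data frame with columns `engine`, `N`, `K`, `seconds`.
#' @export
runtime_benchmark <- function(N = 2^(9:12), K = NULL, N_multi = 512,
                              replicates = 3, seed = NULL) {
  with_seed(seed, {
    rows <- list()
    for (n in N) {
      sc <- dyadic_preset(n)
      x <- stats::rnorm(n); y <- stats::rnorm(n)
      tt <- vapply(seq_len(replicates), function(r) {
        st <- dcca_stream(sc)
        unname(system.time(stream_push(st, x, y))["elapsed"])
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(engine = "online_pairwise", N = n, K = 2,
                   seconds = stats::median(tt))
      tt <- vapply(seq_len(replicates), function(r) {
        unname(system.time(dccc(x, y, sc))["elapsed"])
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(engine = "offline_blocked", N = n, K = 2,
                   seconds = stats::median(tt))
    }
    for (k in K %||% integer(0)) {
      sc <- dyadic_preset(N_multi)
      Xm <- matrix(stats::rnorm(N_multi * k), ncol = k)
      tt <- vapply(seq_len(replicates), function(r) {
        unname(system.time({
          for (a in seq_len(k - 1)) for (b in (a + 1):k) {
            st <- dcca_stream(sc)
            stream_push(st, Xm[, a], Xm[, b])
          }
        })["elapsed"])
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(engine = "sequential_pairwise", N = N_multi, K = k,
                   seconds = stats::median(tt))
      tt <- vapply(seq_len(replicates), function(r) {
        unname(system.time({
          st <- dcca_stream_multi(k, sc)
          stream_push(st, Xm)
        })["elapsed"])
      }, 0)
      rows[[length(rows) + 1L]] <-
        data.frame(engine = "matrix", N = N_multi, K = k,
                   seconds = stats::median(tt))
    }
    do.call(rbind, rows)
  })
}
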