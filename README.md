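# rtdcca — real-time detrended cross-correlation analysis

`rtdcca` estimates scale-free coupling between nonstationary signals *as
they arrive*. It implements detrended cross-correlation analysis (DCCA),
detrended fluctuation analysis (DFA) and the detrended cross-correlation
coefficient (DCCC) in a one-pass, constant-memory form, for a signal pair
or for all pairs among K channels at once — the setting of, e.g., online
EEG functional-connectivity monitoring, where a new connectivity estimate
is wanted every couple of seconds without storing or re-scanning the
recording.

## The statistic

Both series are integrated into profiles $X(t)=\sum_{i\le t}x(i)$. At each
window size (scale) $s$ the profiles are cut into windows, each window is
detrended by its own least-squares line, and the covariance of the
residuals defines the scaling function $F^2_{DCCA}(s)$; with a series
against itself this is the squared DFA fluctuation function
$F^2_{DFA}(s)$. The coefficient
$$\rho_{DCCA}(s)=\frac{F^2_{DCCA}(s)}{F_{DFA,x}(s)\,F_{DFA,y}(s)} \in [-1,1]$$
is a per-scale analogue of Pearson's r valid for nonstationary signals,
and the log-log slopes of $F_{DFA}(s)$ give the scaling exponents
$\alpha$.

The streaming engines maintain, per scale, a few running sums of the
profiles ($\sum X$, $\sum iX$, $\sum XY$, $\sum X^2$, ...) over the
currently filling window. When a window fills, its detrended covariance is
produced in closed form from those sums alone, the sums reset, and a ring
of completed blocks implements a circular analysis window of length `W`:
the first estimate appears after `W` samples, then every `s_max` samples.
Memory never depends on how much signal has been seen. The matrix engine
(`dcca_stream_multi()`) does the same for K channels simultaneously with
vector/outer-product accumulators, yielding the full
$K \times K \times n_s$ coefficient array plus per-channel $\alpha$, and
matches running all pairwise engines bit for bit.

Offline two-pass references (`dcca_blocked()`, `dcca_sliding()`,
`dccc()`), an mc-ARFIMA simulator of pairs with known cross-persistence
(`simulate_mc_arfima()`, exponent $\lambda=(d_2+d_3+1)/2$), contamination
tools (`add_white_noise()`, `add_spikes()`) and evaluation drivers
(`precision_experiment()`, `noise_experiment()`, `runtime_benchmark()`)
complete the package.

## Worked example

Simulate a strongly cross-persistent pair (defaults: $d_2=d_3=0.3$,
innovation correlation 0.9, so $\lambda = 0.8$) and analyse it offline:

```r
library(rtdcca)
p  <- simulate_mc_arfima(1024, seed = 7)
sc <- dyadic_preset(1024)          # scales 2^2..2^8, W = N
d  <- dcca(p$x, p$y, sc)
d
#>  scale       F2_xy        F2_x        F2_y       rho
#>      4   0.1392330   0.1644902   0.1601053 0.8579644
#>      8   0.4756973   0.5598823   0.5596561 0.8498096
#>     16   1.3978472   1.7671341   1.5805667 0.8364087
#>     32   3.6202917   4.8060951   4.1991247 0.8058756
#>     64  11.1280717  13.6352100  12.7824042 0.8429129
#>    128  34.9528483  40.0476913  38.9994042 0.8844328
#>    256 112.2201020 140.6342357 109.2274769 0.9054390
attr(d, "lambda")   # 0.7921 — close to the theoretical 0.8
```

`rho` near 0.85 across scales says the pair shares most of its scale-free
fluctuation at every time scale; the fitted `lambda`/`alpha` slopes
quantify how the fluctuation amplitudes themselves grow with scale.

The same coefficients in real time, emitted every `s_max = 128` samples
over a sliding 512-sample window:

```r
st <- dcca_stream(scale_set(8, 128, W = 512))
ests <- stream_push(st, p$x, p$y)   # 5 estimates for 1024 samples
stream_estimate(st)$rho             # latest per-scale coefficients
```

With `W = N` the streaming estimate reproduces the offline blocked
estimate to MSE ~ 1e-23. A 14-channel EEG-style stream works the same way
through `dcca_stream_multi(14, scale_set())` (defaults: scales 8..128,
`W = 512`, i.e. 2-second updates at 256 Hz).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/rtdcca.R simulate --n 4096 --seed 1 --out pair.csv
Rscript inst/cli/rtdcca.R analyze --in pair.csv --engine matrix --out est.csv
tail -n +2 pair.csv | Rscript inst/cli/rtdcca.R stream --smin 8 --smax 128 --W 512
```

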