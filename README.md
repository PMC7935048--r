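# fbconn — filter-banked functional network connectivity

`fbconn` estimates time-varying functional network connectivity (dFNC) from
component time courses (e.g., ICA networks from resting-state fMRI) by
performing frequency tiling **directly in the connectivity domain**. It is
aimed at researchers who use sliding-window correlation state analyses and
want to stop assuming that connectivity only changes slowly.

## The idea

Sliding-window Pearson correlation (SWPC) over a window of `2Δ+1` samples can
be rewritten as a two-stage system. Stage one turns a pair of series into the
per-sample normalized product

```
w(t) = [x(t) − μx(t)]/σx(t) · [y(t) − μy(t)]/σy(t)
```

with windowed moments `μ`, `σ`; stage two convolves `w(t)` with the
rectangular window kernel. The rectangle is a low-pass filter — SWPC throws
away every high-frequency component of connectivity by construction.

`fbconn` keeps stage one and replaces stage two with a bank of `N` stable
zero-phase IIR band filters `h_n` tiling `[0, Nyquist]`:

```
r_n(t) = (h_n * w)(t),   n = 1 … N
```

so connectivity is estimated in every frequency band at once, static FNC
(band 1 contains 0 Hz) and fast dynamics in one framework. Band-filtered
observations are clustered into connectivity states (k-means++, best of 30
restarts), each state gets a per-band **fraction-rate frequency profile**,
and fraction rates can be compared between two groups with
Benjamini–Hochberg FDR control. A multivariate-normal simulator with
oscillating, state-switching covariance provides ground truth for
validation.

Defaults mirror the reference analysis: 11-sample window, 10 Chebyshev
type-2 bands (≥ 30 dB stopband, ≤ 3 dB passband, forward–backward filtered),
k = 8 states.

## Worked example

Simulate the toy scenario in which connectivity oscillates too fast for a
31-sample window (preset "D": state 1 at 0.01 cycles/sample, state 2 at
0.07), then run both estimators and score recovery against the known ±A
patterns:

```r
library(fbconn)
scn <- toy_scenario_preset("D", duration = 5000, seed = 3)
rep <- run_toy_scenario(scn)
print(rep)
#> FBC matched centroid correlations: 0.996, 0.998, 0.985, 0.995 (mean 0.994)
#> SWPC matched centroid correlations: 0.997, 0.999, 0.576, 0.503 (mean 0.769)
#> FBC band fractions of matched clusters:
#>     band1 band2
#> +A1 0.199 0.061
#> -A1 0.204 0.060
#> +A2 0.520 0.564
#> -A2 0.077 0.315
```

Both estimators recover state 1 (its 0.01 cycles/sample oscillation sits
inside the sliding window's main lobe, correlations ≈ 1.0). State 2
oscillates at 0.07 — beyond the 31-sample window's lobe — so SWPC's two
state-2 centroids degrade to 0.58/0.50 while the band-filtered estimates stay
at 0.99. The fraction-rate table adds the frequency readout: the ±A1 clusters
spend their time in band 1 (0.20 vs 0.06), the ±A2 clusters in band 2.

On real data the entry point is `run_pipeline()` (or the `inst/cli/fbc`
script): delimited time-series files in, fraction-rate tables, state
centroids, group comparison and a reproducibility manifest out.

```r
config <- run_config(tr_seconds = 2, window_samples = 11, k = 8, seed = 1)
run <- run_pipeline(c("sub1.tsv", "sub2.tsv"), config,
                    groups = c(sub1 = "patient", sub2 = "control"),
                    output_dir = "fbc_out")
```

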