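---
title: "Filter-banked connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-banked connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbconn)
```

## The model

Functional network connectivity (FNC) analyses usually start from component
time courses $x_i(t)$ (e.g., ICA networks from resting-state fMRI) and ask how
the correlation between pairs of components changes over time. The workhorse
estimator, sliding-window Pearson correlation (SWPC), computes the sample
correlation $r_{x,y}(t)$ over a window of $2\Delta + 1$ samples centered at
each $t$.

`fbconn` builds on a system view of that estimator. Define per-sample windowed
z-scores $z_x(t) = (x(t) - \mu_x(t)) / \sigma_x(t)$, where $\mu_x(t)$ and
$\sigma_x(t)$ are the mean and (population-form) standard deviation over the
window centered at $t$, and form the **pair product trajectory**

$$w(t) = z_x(t)\, z_y(t).$$

The rectangular moving average of $w(t)$ — i.e., the convolution of $w$ with
the window kernel, normalized by the window length — approximates SWPC, and
equals it exactly when the windowed moments are replaced by global moments
(`swpc_via_convolution()` vs. `swpc()`; both identities are asserted in the
test suite). The rectangular kernel is a low-pass filter, so SWPC only ever
sees the low-frequency content of $w(t)$: the *connectivity-domain* spectrum
is truncated regardless of how the *activity-domain* spectrum was
preprocessed.

Filter-banked connectivity replaces the single rectangular kernel with a bank
of $N$ band filters $h_n$ tiling $[0, f_\mathrm{Nyquist}]$:

$$r_{n,x,y}(t) = (h_n * w)(t), \qquad n = 1, \dots, N,$$

so every frequency band of connectivity — including the zero-frequency band
that corresponds to static FNC — is estimated on equal footing, in the time
domain.

## Filter design

The default bank (`filter_design_spec()`) uses **Chebyshev type 2** IIR
filters: flat passband, equiripple stopband, far lower order than an FIR
design of comparable selectivity. Parameters, with defaults:

* `n_bands = 10`: contiguous equal-width bands over $[0, 1/(2\,\mathrm{TR})]$.
  With TR = 2 s this gives band 1 = 0–0.025 Hz, band 2 = 0.025–0.050 Hz, …,
  band 10 = 0.225–0.250 Hz. The choice is analogous to picking an FFT length.
* `stopband_atten_db = 30`, `passband_ripple_db = 3`: the design spec each
  realized single-pass response must meet.
* `transition_fraction = 0.25`: stopband edges sit this fraction of the band
  width beyond each passband edge. The value keeps transition bands
  proportional to band width and filter orders modest (5–6 for the default
  bank's low/high-pass ends, 10 poles for interior band-passes).
* `family`: `"butterworth"` and `"elliptic"` are available for robustness
  comparisons; results should be, and in our checks are, qualitatively
  unchanged.

Order selection follows the classical Chebyshev order formula after bilinear
pre-warping; band-pass bands use the geometric-symmetry band transformation.
The stopband edges actually handed to the design are then pulled inward
(toward the passband) to the point where the realized passband loss just
meets the 3 dB spec, refined by bisection against the measured response. This
matters for two reasons. First, designing interior bands directly at the raw,
arithmetically symmetric stopband edges violates the passband spec (the
band transform is geometrically, not arithmetically, symmetric). Second, it
places each band's crossover with its neighbours near −3 dB single-pass,
i.e. one half power after forward–backward filtering — which is exactly the
condition for the band outputs to sum back to the input. The measured
band-sum reconstruction error on broadband noise is ~4–5% relative L2
(asserted ≤ 10% in the tests).

Filters are stored and applied as **second-order sections** (SOS), never as
flat transfer-function polynomials — high-order IIR polynomials are
numerically fragile. Stability (all poles strictly inside the unit circle)
and the realized specs are measured on a dense (≥ 4096-point) frequency grid
at build time; a violation is a hard error naming the band and the measured
values. Zero-phase application (`zero_phase_filter()`) runs each filter
forwards then backwards with odd-reflection padding of $3 \times
\max(\mathrm{order}, 8)$ samples per end, so phase distortion cancels and the
effective magnitude response is the squared single-pass response (stopband
attenuation doubles to ≥ 60 dB).

```{r bank}
bank <- build_filter_bank(filter_design_spec(sampling_hz = 0.5))
bank
```

## States, fraction rates, and group comparison

Banded trajectories from all subjects and bands are concatenated into one
observation matrix (rows = time points, features = component pairs) and
clustered with k-means (squared Euclidean distance, k-means++ seeding, 30
restarts, best model by within-cluster sum of squares; `cluster_states()`).
Defaults follow the reference analysis: an 11-sample window for the moments
behind $w(t)$ and $k = 8$ states, with `elbow_curve()` available for choosing
$k$. Features are clustered raw; standardization is available
(`scale_features`) but off by default, since the filtered connectivity values
share a common scale by construction.

The **fraction rate** of a state is the share of a subject's time points
assigned to it, computed per band and across bands (`fraction_rates()`). A
state's fraction rate as a function of band is its connectivity *frequency
profile* — the piece of information a single-window estimator cannot provide.
Rows with missing values (zero-variance windows) are excluded from clustering
and from fraction-rate denominators, with counts logged in the run manifest.

Two-group comparison (`compare_fraction_rates()`) uses Welch's
unequal-variance t-test per state by default — the reference analysis does
not pin down its test statistic, so the robust default is used and
Mann–Whitney is offered as an option — with Benjamini–Hochberg FDR correction
across the $k$ states (per band, across states within each band).

## The toy simulator

`simulate_toy()` draws six zero-mean, unit-variance series from
$X(t) \sim \mathcal{N}(0, \Sigma(t))$ with
$\Sigma_{ij}(t) = \delta_{ij} + A_{ij} \cos(2\pi f_\mathrm{corr} t)$,
switching between two states (default 10,000 samples each). Connectivity thus
*oscillates* between $+A$ and $-A$ at a frequency $f_\mathrm{corr}$ that is a
property of the connectivity domain, not of the activity spectrum (each
sample is independent; the activity spectrum is white).

Validity requires $\Sigma(t) \succ 0$ at every phase, i.e.
$\max |\mathrm{eig}(A)| < 1$. This rules out dense block patterns with large
amplitudes: a two-block matrix with 0.6 within and −0.3 between blocks has
spectral radius 2.1 and is rejected by `toy_state_spec()` (specs are
rejected, never silently projected back to PD, which would change the ground
truth). The shipped defaults are therefore **three disjoint strong pairs per
state** — state 1 couples (1,2), (3,4), (5,6) and state 2 couples (1,4),
(2,5), (3,6), both at amplitude 0.9 — giving spectral radius 0.9, a minimum
$\Sigma$ eigenvalue of 0.1 at the extreme phase, and a cross-correlation of
only −0.25 between the two vectorized patterns. Sampling uses the symmetric
square root of $\Sigma(t)$ through the eigendecomposition of $A$, vectorized
over time.

Each state contributes two ground-truth centroids ($\pm A$), so the toy
analysis clusters into $k = 4$ and scores recovery by optimally matching
estimated to reference centroids (`match_states()`, exact assignment) and
reporting the matched correlations.

The six presets (`toy_scenario_preset()`) place the two state frequencies
relative to a deliberately partial two-band bank (low-pass 0–0.025,
band-pass 0.025–0.09 cycles/sample) and to the SWPC main lobe (≈ 1/window):

| preset | window | $f_1$, $f_2$ | placement |
|---|---|---|---|
| A | 11 | 0.01, 0.07 | one state per band; both under the window's lobe |
| B | 11 | 0.005, 0.02 | both in the low band |
| C | 11 | 0.04, 0.07 | both in the high band |
| D | 31 | 0.01, 0.07 | state 2 beyond the (too-long) window's lobe |
| E | 31 | 0.005, 0.02 | both within the long window's lobe |
| F | 31 | 0.04, 0.07 | both beyond the long window's lobe |

What passing these scenarios shows — and what it does not: the simulator has
white activity spectra, no hemodynamic smoothing, no measurement noise, and
abrupt state switches. Success here demonstrates the estimator's frequency
logic (band-filtered estimation recovers oscillating states wherever their
frequency lands, while the windowed estimator degrades once a frequency
leaves its main lobe, and the per-band fraction rates localize each state's
frequency), not performance on real BOLD data.

## Numerical choices and conventions

* Pair ordering is row-major upper-triangle: (1,2), (1,3), …, (1,C), (2,3),
  … everywhere (`pair_index()`, `vectorize_fnc()`); mixing this with R's
  column-major `upper.tri()` silently scrambles features against references,
  so the convention is centralized and tested.
* Windowed quantities use valid support only (trajectories shrink by $\Delta$
  per edge); activity series are never zero-padded.
* $\sigma(t) = 0$ in a window produces a missing value and a warning, not an
  error; downstream stages drop such rows and report counts.
* Windowed standard deviations use the population divisor $2\Delta + 1$, and
  `swpc()` computes exact sample Pearson correlation (clamped to $[-1, 1]$
  against roundoff).
* Exported text (time series, trajectories, filter coefficients in JSON) is
  formatted as `%.17g`, so write-then-read round trips are value-exact.
* All randomness flows from one root seed, split deterministically per stage;
  re-running a pipeline with the same config and seed is byte-identical.
* Realized filter specs carry a 0.05 dB measurement grace used only when a
  design edge coincides with the nominal stopband edge (partial custom
  tilings); the default full tiling meets both specs strictly.

## Problem sizes used in the tests

Unit tests run on series of a few hundred samples. The scenario-recovery
suite runs all six presets at 5,000 samples per state over five seeds with
the full 30-replicate clustering protocol; Monte-Carlo checks (windowed
correlation consistency, FDR control under the global null at $m = 8$,
$q = 0.05$, 1,000 replications) use sizes chosen so their binomial /
standard-error bounds are meaningful.

## Limitations

* The windowed-moment front end is shared with SWPC: if means or variances
  move faster than the window can track, $w(t)$ is biased for any band.
* High bands estimate whatever energy is there, including noise; the method
  deliberately makes no prior claim about where connectivity lives, so
  interpretation of high-band states should lean on the fraction-rate
  profiles and on controls such as `highpassed_swpc_scenario()`.
* k-means with Euclidean distance treats all pairs equally and knows nothing
  about estimation uncertainty; alternative clusterings are out of scope.
* Group comparison covers exactly two groups without covariate adjustment.
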