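---
title: "Estimating multivariate transfer entropy: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating multivariate transfer entropy: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvte)
```

## The quantity being estimated

Consider `M` jointly stationary processes, a designated *target* `Y`, a
*source* `X`, and the remaining processes collected in a conditioning vector
`Z`. The conditional (partial) transfer entropy from `X` to `Y` given `Z` is
the information the past of `X` adds about the present sample of `Y` beyond
what the past of `Y` itself and the past of `Z` already provide:

$$
TE_{X \to Y \mid Z} \;=\; H\!\left(Y_n \mid Y^-, Z^-\right) \;-\;
H\!\left(Y_n \mid X^-, Y^-, Z^-\right),
$$

a difference of two conditional entropies (equivalently a sum of four
Shannon entropies, or the conditional mutual information
$I(Y_n; X^- \mid Y^-, Z^-)$). All values are reported in nats. The
conditional form rules out information that merely travels through `Z`,
which is what makes the measure usable for directed-network inference among
more than two series. For jointly Gaussian processes the measure reduces to
half the log-ratio of restricted and unrestricted regression residual
variances, i.e. to (linear) Granger causality — a correspondence the test
suite exercises directly.

The infinite pasts `X^-, Y^-, Z^-` must be truncated to a finite
*embedding*. The package implements the two strategies it compares:

* **Uniform embedding (UE)** — every involved series contributes the fixed
  lags `m, 2m, ..., d*m` (`uniform_embedding()`). Transparent, but the
  dimension grows as `d × M` whether or not the terms are informative.
* **Non-uniform embedding (NUE)** — a greedy forward selection over a
  candidate set of individual `(series, lag)` terms (`build_candidate_set()`,
  `nue_select()`). At each step every remaining candidate is scored by the
  information it adds about the target given the terms already kept —
  conditional-entropy decrease for the linear and binning estimators,
  nearest-neighbor conditional mutual information for the neighbor
  estimator — and the best candidate is admitted only if it passes a
  randomization test. Selection stops at the first rejection. Transfer
  entropy toward the target is then computed once per driver from the single
  selected embedding: drivers with no selected term get TE exactly 0 and are
  deemed non-significant; drivers with at least one selected term get
  `TE = CE(restricted) − CE(full) > 0` and are deemed significant.

All entropies inside one TE evaluation are computed on the same observation
rows, anchored at the maximum lag of the governing candidate set, so the
difference of conditional entropies is internally consistent even when the
selected lags are small.

## The three estimators

**Linear (LIN).** Ordinary least squares without intercept (all series are
standardized first), `TE = ½ log(σ²_restricted / σ²_unrestricted)`. Under
uniform embedding the order is chosen by BIC on the full vector
autoregression (`select_order_bic()`); significance uses the parametric
F-test on the driver's coefficients (`f_test_lin_ue()`). Under non-uniform
embedding the order emerges from the selection itself.

**Binning (BIN).** Each standardized series is quantized once into `Q`
equal-width levels over its observed range (`quantize()`; the global maximum
closes the top bin, so both extremes are always occupied). Entropies are
plug-in sums over occupied hypercubes (`bin_entropy()`), with no bias
correction. `Q = 6` by default. The plug-in estimate makes conditioning
monotone, so BIN transfer entropies are never negative.

**Nearest neighbor (NN).** A Kraskov-style estimator: the distance to the
`k`-th neighbor in the highest-dimensional joint space sets a per-point
radius, and the lower-dimensional entropy terms are obtained from strict
range counts in the projected subspaces, combined through digamma functions
(`nn_cmi()`). Sharing the radius across the four terms cancels most of the
dimension-dependent bias. Defaults: `k = 10`, maximum (Chebyshev) norm, for
which the unit-ball volume constant is 1; the Euclidean norm is available.
Raw NN estimates may be slightly negative; values are reported unclamped.

The neighbor searches are exact brute-force scans accelerated by projection
pruning (sorting along one coordinate and stopping a scan once that single
coordinate's gap exceeds the current radius), implemented in C++. The
pruned search is bit-identical to a full scan — asserted in the tests
against an independent distance-matrix implementation — and keeps a full
non-uniform analysis of a five-series, 512-sample realization in the
seconds range on one core.

## Significance machinery

* **LIN UE:** parametric F-test at level `alpha` on the driver's
  coefficients.
* **BIN/NN UE:** time-shift surrogates — the driver's series is circularly
  rotated by a lag drawn uniformly from `[min_shift, N − min_shift]`
  (default `min_shift = 20`, chosen to outlast short-range autocorrelation),
  the embedding columns are rebuilt, and TE is recomputed; the observed TE
  must strictly exceed the `100(1−alpha)` nearest-rank percentile of
  `n_null` surrogate TEs (default 100). Circular shifting preserves the
  marginal distribution and autocorrelation of the surrogate series exactly;
  surrogates are built by shifting the raw series and re-extracting lagged
  columns, which also preserves the within-driver lag structure.
* **NUE candidate test:** the winning candidate's selection statistic is
  compared with `n_null` randomized replicates — time-shifted copies of the
  candidate column for LIN/BIN, independent shuffles of both the candidate
  and the target for NN — and admitted when it strictly exceeds the
  `100(1−alpha)` nearest-rank percentile. `p_like` values are reported as
  `(1 + #{null ≥ stat}) / (1 + n_null)` so they are never exactly zero.

### The multiplicity question in the candidate test

The per-step candidate test is calibrated for a *single* candidate: with
one candidate and `alpha = 0.05` it accepts a junk term in ≈ 5% of runs
(the suite verifies this over 200 seeds). But the tested term is the
*maximum* over `m` remaining candidates, and for serially uncorrelated
data (25 white-noise candidates) the uncorrected rule admits a first junk
term in roughly 70% of runs. In autocorrelated systems the effect is much
milder, because time-shift nulls inherit the variance inflation of
dependent-sample statistics and widen accordingly — which is why the
uncorrected rule still achieves ~0.94 pooled specificity on the five-series
benchmarks — but the guarantee that a structureless target yields an empty
embedding does not survive greedy maximization.

`nue_params(mult_adjust = TRUE)` therefore offers a Bonferroni-corrected
mode: the winner is tested at level `alpha/m`, with the null sample
enlarged to `ceil(m/alpha) − 1` replicates so the corrected nearest-rank
percentile is resolvable (null evaluation stops early as soon as rejection
is certain). In the corrected mode a 25-candidate white-noise target comes
back empty in ≈ 95% of runs, at the price of reduced sensitivity for weak
links (on the non-linear benchmark, pooled sensitivity 0.84 versus 0.93
uncorrected). The uncorrected rule is the default because it is the
procedure under study and reproduces the benchmark operating points; the
corrected mode is used where the empty-embedding guarantee is the property
of interest, including the estimator-agreement study below.

## Benchmark simulators

Three seeded generators with programmatic ground truth
(`ground_truth()`), used by the tests and reproduction script; all discard
a 1000-sample burn-in (transient removal) and guard against divergence with
bounded reseeding.

**Coupled chaotic maps** (`simulate_coupled_maps()`): two noisy quadratic
maps `f(v) = 1 − 1.8 v²` with convex-combination coupling `1 → 2` at lag 1
and Gaussian dynamical noise. Defaults `coupling = 0.3`,
`noise_coeff = 0.01`: the coupling must stay below this map family's
identical-synchronization threshold (~0.37), because under synchronization
the target's own past predicts its present as well as the driver's past
does and the transfer entropy vanishes; 0.3 sits in the middle of the
robustly detectable sub-threshold range.

**Linear AR network** (`simulate_linear_ar5()`): five Gaussian
autoregressive series — a resonant AR(2) oscillator (coefficients
`0.95√2`, `−0.9025`) driving nodes 2 (lag 2), 3 (lag 3) and 4 (lag 2), plus
a lag-1 feedback pair `4 ↔ 5` with weights `±0.25√2`; unit-variance
innovations. Interactions extend up to three samples into the past; the
companion-form spectral radius is 0.95 (`ar5_spectral_radius()`), asserted
in the tests.

**Non-linear AR network** (`simulate_nonlinear_ar5()`): identical skeleton,
but the `1 → 2` coupling acts through the *squared* driver sample. The
square of a symmetric linear process is uncorrelated with the process's
past, so this link is invisible to the linear estimator while remaining a
strong dependence for the model-free ones — the property the benchmark
exists to expose.

What these generators emulate — and what they do not: they produce
stationary, regularly sampled, noise-driven dynamics with known directed
structure, which is exactly the regime the estimators assume. They do not
emulate nonstationarity, measurement noise, volume conduction / instant
mixing, missing data, or heavy-tailed marginals, so green tests here say
nothing about robustness to those features of real recordings; the
instantaneous-effects option (`instantaneous` sets, lag-0 candidates) is
provided for measurement conventions that permit same-sample influence, but
the benchmarks do not exercise it.

## Study conditions used by tests and the reproduction script

Chosen once as a desk-scale version of the full study (which uses 100
realizations throughout) and fixed:

* Coupled maps: 100 realizations × 512 samples, BIN UE, max lag 1,
  100 surrogates, `alpha = 0.05`, `Q = 6`.
* Linear network: 20 realizations × 512 samples; LIN UE (BIC order, max lag
  5) versus BIN UE with the full 25-term uniform embedding.
* Non-linear network: 20 realizations × 512 samples; BIN NUE and NN NUE
  (max lag 5, `Q = 6`, `k = 10`) versus the linear methods.
* Estimator agreement on Gaussian data: 4 realizations × 1024 samples,
  non-uniform methods in corrected mode; agreement measured as the rank
  correlation of per-pair mean TE (and their absolute difference).
* Calibration: 200 seeds for the surrogate and single-candidate tests,
  40 seeds for the white-noise empty-embedding property.

## Numerical choices and degenerate inputs

* Normalization uses the population (1/N) variance; estimators operate on
  normalized series uniformly (the linear TE is invariant to affine
  rescaling, so this only matters for the quantizer's range and the
  neighbor metric).
* Quantization assigns boundary samples to the lower bin except the global
  maximum; constant series are rejected with an error naming the series.
* Joint symbol states are coded incrementally in exact double arithmetic
  and re-factorized before `2^52` so any embedding dimension is countable
  without hashing collisions.
* Tie-breaks: the greedy argmax resolves ties toward the lowest enumeration
  index (series-major, lag-ascending); percentile thresholds use the
  nearest-rank convention with strict exceedance, which is conservative
  under ties.
* Duplicate points in neighbor searches are counted under the strict
  inequality rule with no jitter added (deterministic results preferred);
  all-identical samples raise an error.
* Rank-deficient linear designs fall back to the minimum-norm solution with
  a warning; a zero unrestricted residual variance yields `+Inf` TE with a
  warning.
* Empty embeddings are a valid NUE outcome: TE is exactly 0 and
  non-significant by convention.
* All randomness flows through R's RNG (including inside the C++ null
  loops), so every verdict, trace and batch is reproducible from a seed.

## Known limitations

* No multiple-testing correction is applied across the `M(M−1)` directed
  pairs of a network analysis; controlling the network-level error rate is
  the user's responsibility.
* The BIN estimator's equal-width bins lose resolution when a target mixes
  components of very different amplitude; weak incoming links to such
  targets are the first to drop below detectability.
* NN estimates in high-dimensional uniform embeddings (e.g. 25 terms at 512
  samples) are strongly biased toward zero — the curse-of-dimensionality
  failure mode the non-uniform strategy exists to avoid; comparisons between
  estimators should be made on selected embeddings.
* Only stationary formulations are implemented; no detrending, filtering or
  stationarity testing is performed beyond an integer downsampling
  pass-through.
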