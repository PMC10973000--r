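---
title: "Methods: detrended covariance features for Riemannian MI decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detrended covariance features for Riemannian MI decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccabci)
```

This vignette documents the models and procedures implemented in `dccabci`,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the synthetic benchmarks demonstrate.

## The decoding model

An EEG epoch (n channels × N samples; 1 s windows by default) is summarized
by an SPD feature matrix and classified by minimum distance to per-class
Karcher means under the affine-invariant Riemannian metric (AIRM). Two
feature estimators are provided:

* **Shrinkage sample covariance** (`shrinkage_scm()`): the Ledoit–Wolf
  analytic convex combination of the sample covariance with a scaled
  identity. The shrinkage intensity is estimated from the data and
  guarantees positive definiteness even with fewer samples than channels.
  Note that when the true covariance *is* spherical the estimated intensity
  legitimately approaches 1 (both the target and the SCM converge to the
  same matrix); intensity vanishes asymptotically only for anisotropic
  covariance, which is the relevant EEG regime.
* **DCCA matrix** (`dcca_matrix()`): pairwise detrended covariances at scale
  `s`. Each length-`s` window is linearly detrended (two-parameter OLS —
  higher orders are out of scope) independently per channel, and residual
  covariances are averaged over windows. Sliding (step 1, `K = N − s + 1`
  windows) and non-overlapping (`K = floor(N/s)`) window modes are
  available; sliding is the default because it is the variant with an exact
  streaming counterpart. For covariance features the cumulative-sum profile
  step of classical DCCA/DFA is omitted — the purpose is denoising the
  covariance of the native signal, not estimating fractal coupling — while
  DFA mode (`integrate = TRUE`) applies it.

Both features are trace-normalized by default before classification. This
removes amplitude scale (for the SCM) and, for DCCA, the window-averaging
convention: the per-window mean uses a `1/(K − 1)` prefactor, which is a
pure global scale factor. (For the degenerate single-window case `K = 1` the
implementation returns the lone window value, i.e. divides by
`max(K − 1, 1)`.) Whether to shrink or trace-normalize DCCA features is
genuinely open; the package exposes both toggles and defaults to
trace-normalization without shrinkage, since the DCCA Gram construction is
already positive semi-definite and the ridge repair handles rank
deficiency explicitly (default ridge `1e-10` relative to the mean diagonal,
always recorded in the result's `repair` attribute — silent repair would
mask broken preprocessing upstream).

### Streaming estimation

With the scale fixed, the residual-forming projector `M = I − H` of the
linear detrend is constant, so each new sample closes exactly one new
sliding window and adds `W M Wᵀ` (computed through the rank-2 identity
`x'My = x'y − (Xd'x)'(Xd'Xd)^{-1}(Xd'y)`) to a running accumulator.
`stream_update()` therefore has per-sample cost independent of the samples
seen and stores only the last `s` samples per channel plus an n×n
accumulator; its output equals the batch sliding computation to floating
point roundoff. The batch path exploits the same rank-2 structure: the
window sums it needs reduce to cumulative sums and one
multiplicity-weighted Gram matrix, `O(nN + Kn²)` per epoch.

### Recentering and adaptation

`rebias(C, R) = R^{-1/2} C R^{-1/2}` aligns feature distributions across
sessions; it preserves pairwise AIRM distances and maps a set's Karcher
mean to the identity when `R` is that mean. Three evaluation schemes are
implemented in `pseudo_online_replay()`: none, fixed-reference rebias, and
causal adaptive recentering. The adaptive update as printed in the source
material is ambiguous at its second step (its piecewise cases overlap), so
both readings are implemented: the default `"as_printed"` variant rebases
the reference to the first test matrix and then moves it along the geodesic
toward each incoming matrix with step `1/(i − 1)`; the `"running_mean"`
variant starts from the training reference and uses step `1/i`. Both rebias
an incoming matrix *before* absorbing it, so predictions are causal: no
future epoch influences an earlier one (asserted by a prefix-invariance
test).

## The trial protocol and metrics

Online command delivery accumulates evidence by exponential smoothing,
`e ← (1 − α)e + α p`, with α = 0.05 per 62.5 ms update, evidence reset to
0.5 at trial start, per-class thresholds in (0.5, 1] (default 0.7 — neither
sample-wise metrics nor the timeout-normalized κ depend on the threshold),
and a 7 s timeout. The right-hand probability in the smoothing recursion is
taken as the instantaneous classifier probability (any other reading makes
the recursion vacuous). MDM distances are mapped to probabilities by a
softmax over negative distances at temperature 1: the mapping is
unspecified upstream; softmax is bounded, monotone in the decision rule,
and leaves the argmin unchanged. Boundary conventions are conservative and
documented: evidence exactly at 0.5 counts as *not* toward the truth for
bar dynamics, and a timeout with the bar exactly at 0.5 counts as an error
in approximate accuracy.

Chance level uses the inverse binomial CDF: the smallest `k/n` whose
cumulative probability under uniform guessing reaches `1 − α` (α = 0.001).
Because `k` is an integer, the threshold is not strictly monotone in `n`
over consecutive values (e.g. it rises from n = 10 to n = 11); monotonicity
holds on coarser grids and is tested there. Likewise, the timeout-normalized
κ satisfies `|κ_norm| ≤ |κ|` — stated as `κ_norm ≤ κ` it would be false for
negative κ.

Group-level comparisons route through a Friedman test, pairwise Wilcoxon
signed-rank tests with Benjamini–Hochberg adjustment, and Lilliefors
normality screening; the post-hoc contrasts (`contrast_connections()`,
`dfa_topography()`) use a Lilliefors-at-0.05 rule to select paired t vs
Wilcoxon per connection/channel (the selection level is a package choice;
the rule itself is prescribed), deliberately without multiplicity
adjustment, as the analyses are exploratory. With fewer than 4 pairs
normality cannot be assessed and the t-test is used; all-zero paired
differences return p = 1.

## Fractal analyses

`dfa_exponent()` regresses `log F(s)` on `log s` (natural logs; the slope
is base-invariant) over dyadic scales 16–256 by default, with the profile
step applied, using non-overlapping windows (the traditional DFA
convention; sliding is available). `dccc()` normalizes `F²_xy` by the two
self-fluctuations, giving a bounded coupling coefficient; overshoots beyond
1 by more than `1e-10` are treated as errors rather than clipped.

## The synthetic generator

`session_spec()` / `generate_session()` emulate a two-class, 22-channel,
512 Hz MI recording: four runs of 20 balanced trials, 6.5 s of imagery per
trial with 2 s rests. Oscillatory activity is 8–30 Hz band-passed Gaussian
noise (not sinusoids, avoiding degenerate covariance), mixed across
channels by a fixed subject-level matrix; the left class multiplies
oscillatory variance at C4 by 0.5 (0.75 at FC6/CP6), the right class at C3
(FC5/CP5) — a contralateral desynchronization emulation. Each channel adds
fractional Gaussian noise background (Davies–Harte circulant embedding;
default H = 0.7, amplitude 0.5 relative to unit oscillatory SD, emulating
the persistent 1/f-type character of broadband EEG). Optional per-channel
random cubic polynomials span each trial; their amplitude parameter is the
SD over the trial in units of the oscillatory SD. The benchmark "strong
drift" condition uses amplitude 4, chosen so that the *within-epoch* drift
power is comparable to the oscillatory power — the regime local detrending
is designed for, and typical of pronounced electrode drift. Between-session
non-stationarity is a random congruence transform `W = I + 0.25·G/√n`
applied to the second session's data.

What the generator does **not** emulate: realistic ERD time courses,
volume-conduction forward physics, non-Gaussian artifacts (except injected
blinks), inter-subject variability of montage geometry. Passing benchmarks
therefore demonstrate that the pipeline behaves as designed under its own
assumptions (class-dependent spatial covariance plus drift plus session
shift), not that the accuracy figures transfer to real recordings.

## Numerical choices

* Matrix functions use symmetric eigendecompositions with an eigenvalue
  floor of `1e-12`, keeping log/sqrt/powers finite near singularity.
* Karcher mean: fixed-point iteration with unit step from the arithmetic
  mean, tolerance `1e-8` on the mean tangent norm, 50 iterations maximum;
  non-convergence raises a typed condition carrying the last iterate.
* AIRM is evaluated in the congruence-symmetric form
  `‖log(P₁^{-1/2} P₂ P₁^{-1/2})‖_F`, mathematically equal to
  `‖log(P₁^{-1}P₂)‖_F` but numerically symmetric in its arguments.
* Zero-phase filtering is a forward–backward pass of the Butterworth design
  (effective order doubled, zero group delay) over an odd-reflected
  extension spanning 16 periods of the low cutoff, long enough for edge
  transients to decay below `1e-8`; causal filtering keeps explicit
  direct-form-II-transposed state so packet-wise and one-shot outputs are
  bit-identical. No transient is trimmed in causal mode (online semantics).
* Epoch arithmetic is exact: steps are converted to integer sample counts
  (32 at 512 Hz, 10 at 160 Hz for the 62.5 ms step) and non-integer steps
  are rejected. Indexing is 0-based half-open throughout the I/O surface.
* MDM ties break to the first class in declared order; CSP ties (equal
  `|λ − 0.5|`) break by eigenvalue index; LDA tie on the boundary goes to
  the first class. CSP uses the literal reading of "three most
  discriminative filters" (3 filters, not 3 pairs; `n_filters` adjustable)
  and arithmetic class means by default (a Riemannian mean can be passed in
  by the caller, the function only consumes per-class means).
* EDF samples are 16-bit; the writer quantizes against header ranges chosen
  to round-trip exactly (the reader inverts the writer bit-for-bit on the
  stored values).

## Problem sizes in the test suite

The suite keeps simulations at desk scale by choice: the end-to-end
benchmark uses 20 subject seeds × two one-run sessions (20 trials each,
non-overlapping 1 s epochs → 120 epochs/session) rather than the full
four-run layout; DFA recovery uses 200 replicates of length 4096 per Hurst
value; the null-calibration of the contrast pipeline uses 50 repetitions of
8 paired subjects × 5 channels. These sizes are stated here so results are
read at the scale they were computed.

## Known limitations

* The DCCA matrix is positive semi-definite by construction but can be
  numerically rank-deficient for strongly dependent channels; the ridge
  repair restores definiteness at the cost of a documented bias on the
  diagonal.
* The adaptive-reference variants differ in their early-epoch transient;
  with few test epochs the choice can matter. Both are tested, only the
  default is benchmarked.
* Absolute decoding accuracies from the generator are not comparable to
  accuracies on real EEG; only orderings and invariances are asserted.
* The EDF layer targets continuous recordings with one record duration and
  a single annotations channel; discontinuous (EDF+D) files are out of
  scope.
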