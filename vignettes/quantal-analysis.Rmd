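---
title: "Quantal analysis of inhibitory transmission: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of inhibitory transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

## Scope

`synquant` analyses voltage-clamp recordings of inhibitory postsynaptic
currents (IPSCs) at paired recordings from fast GABAergic synapses, and
ships a synthetic-synapse generator whose ground truth validates every
estimator by parameter recovery.  This vignette documents the model, the
estimator definitions, the numerical choices that were genuinely open, and
what a green test does — and does not — establish.

## The generative model

**Pool dynamics.**  A readily releasable pool starts at `N` vesicles.  Each
action potential (AP) releases Binomial(n, Pr) vesicles from the current
pool n.  Between stimuli the pool gains `replenish_rate × interval`
vesicles (stochastically rounded, so the expectation is exact) and is
capped at `N`.  This is the minimal constant-rate single-pool model; there
is no calcium-dependent replenishment, no facilitation, and no
heterogeneity of Pr across release sites (all stated non-goals).  A
consequence worth knowing: the closed form of the pool's recovery after a
depleting train is *linear-saturating*, `n(Δt) = min(n_end + r·Δt, N)`, not
exponential — the exponential recovery observed at real synapses reflects
calcium-dependent replenishment outside this model.  `recovery_fit()`
nevertheless fits the conventional exponential, because that is the model
fitted to experimental recovery data and the quantity reported in the
literature.

**Release times.**  Each synchronously released quantum receives a latency
drawn from the time-course-of-release (TCR) density, parameterized by its
peak (`latency`, ms after the AP peak) and full width at half maximum
(`half_duration`).  Two families are supported: Gaussian (mode = mean;
FWHM = 2√(2 ln 2)·σ, an identity the tests assert exactly) and gamma,
whose (shape k, scale θ) are solved numerically from mode = (k−1)θ and the
requested FWHM (k > 1).  Asynchronous release is an inhomogeneous Poisson
process: constant rate during the train, exponentially decaying after it.

**Quantal waveform.**  The elementary current is the normalized product
form q(t) ∝ (1 − e^(−t/τr))·e^(−t/τd), rescaled so its peak equals the
quantal amplitude.  The functional form is a package decision: it makes
the oracle tests closed-form (peak time τr·ln(1 + τd/τr)), while measured
average quantal currents pass through every kernel-accepting function as
plain sampled vectors.  Default τr = 0.3 ms, τd = 5 ms, amplitude 100 pA —
typical for perisomatic GABAergic currents at ~physiological temperature.

**Amplitude variability.**  Per-quantum amplitudes are jittered
lognormally with mean 1 and CV `quantal_cv` (default 0.3, the conventional
quantal CV at central synapses).  Lognormal keeps amplitudes positive.

**Noise.**  Gaussian white noise low-pass filtered (Gaussian filter,
half-amplitude corner `bandwidth`, default 10 kHz) and rescaled to the
stated SD — emulating a 10 kHz acquisition filter at 20–50 kHz sampling.
Default sampling interval is 0.02 ms (50 kHz); the mini-detection pipeline
uses 0.05 ms (20 kHz), sufficient for the slower spontaneous events.

## Estimators

**Template matching.**  At every offset the unit-peak template is fit to
the trace by least squares with free scale and baseline; the criterion is
scale/SE(scale).  Two deliberate refinements beyond the textbook recipe,
both forced by measurement rather than taste:

1. *Studentization.*  Under band-limited (correlated) noise the nominal SE
   underestimates the criterion spread by ~20%, which floods the detector
   with false positives at the conventional threshold of 4.  The criterion
   trace is therefore rescaled by its own robust (MAD) SD, restoring the
   threshold's meaning in noise-SD units.  The MAD is insensitive to the
   sparse event-related excursions as long as events occupy a small
   fraction of the trace (true for mini recordings; a test documents the
   breakdown at unrealistic event densities).
2. *Run-based peaks.*  The criterion stays above threshold for roughly one
   template length around each event, with noise ripples creating many
   spurious local maxima; one detection is emitted per contiguous
   above-threshold run (runs merged across sub-refractory gaps), at the
   run maximum.  This sets the resolution for superimposed events: events
   closer than about one template length merge, a ~5% undercount at
   3.75 Hz that is inside the 10% validation band.  Overlapping detections
   are retained and flagged, not dropped.

Event amplitude is baseline-to-peak (baseline: 2 ms window ending 0.5 ms
before detection; peak parabola-refined), and the 20–80% rise time uses
linear interpolation at the level crossings.  These conventions — window
lengths, interpolation, the threshold default of 4 and refractory of
1 ms — are package decisions where the method literature is silent.

**Unitary statistics.**  Failures are trials whose post-AP peak stays
below `k = 3` baseline SDs.  Because the raw maximum of a ~20 ms noise
window almost surely exceeds 3 SDs (max statistics), the failure decision
is taken on a 2 kHz-smoothed copy of the segment, whose noise maximum
stays near 1 SD while a genuine IPSC is barely attenuated; amplitude and
latency are still measured on the raw trace.  Failures enter the amplitude
statistics as 0 pA (so a high failure fraction and a low mean amplitude
coexist coherently) and are excluded from latency statistics.  Latency is
AP peak → onset, onset being the interpolated 5%-of-trial-peak crossing;
CV = SD/mean and skewness is the bias-uncorrected g₁ — both asserted
against direct moment oracles to machine precision.

**Deconvolution.**  The averaged train response is deconvolved by the
quantal kernel in the frequency domain with Wiener-style regularization
R = Y·K̄/(|K|² + λ), followed by a unit-DC-gain Gaussian low-pass at 2 kHz
(display convention; the unit DC gain means window integrals are preserved
to <0.5%).  λ is tied to the high-frequency plateau of the trace spectrum
(median power in the top fifth of frequencies, relative to the spectral
peak) with a floor of 1e−10·max|K|², so noiseless round trips conserve
total quanta within 2% — a property test.  The exact regularization of the
original instrument-software implementations is unknown; this scheme is
the package's own and is therefore validated only by ground-truth
recovery.  Release windows are half-open (a, b] — synchronous (0, 5] ms
post-AP, asynchronous (15, 20] ms, post-train > 20 ms after the last AP —
so no sample is counted twice.

**TCR fitting.**  The AP-aligned unitary average is modelled as
content × (TCR density ∗ quantal kernel), minimized in SSE over (latency,
log FWHM, log content) by Nelder–Mead with a multi-start over latencies
0.25–5 ms in 0.25 ms steps (the SSE surface has local minima when the
start is far from the true latency).  The reported "latency" is the
density *peak*; the 5%-rise onset of the fitted density is also reported
as a diagnostic, since the experimental definition is ambiguous between
peak and onset.

**Pool analysis.**  Cumulative normalized amplitudes vs stimulus number;
OLS on the last 10 points; RRP (in units of IPSC₁) = intercept,
refill slope = slope, Pr = 1/intercept.  The estimate is the *pool
decrement*: with replenishment active during the train the intercept
shrinks by approximately the replenished fraction of the steady-state
response, b = r·Δt/(N·Pr).  The validation suite *measures* this bias (at
b ≈ 0.56 the normalized pool drops from 5 to ≈ 2.2) rather than hiding
it — which is also why the parameter-recovery ensembles run at the small
post-train replenishment rate, where b ≈ 0.02.  Quantal size comes from
unconstrained variance–mean regression (slope = q); for binomial release
the slope is biased by ≈ (1 − Pr), another bound the tests assert.  Pr is
reported unclipped with a validity flag.  Absolute conversion multiplies
by the quantal content of IPSC₁ (= IPSC₁/q); the per-ms refill rate
divides the per-stimulus slope by the inter-stimulus interval — this
conversion convention is the package's own, because the unit of the
corresponding published quantity is internally inconsistent with a
single-pool bookkeeping and could not be reverse-engineered with
certainty.

**Recovery fitting.**  A(Δt) = A∞ − (A∞ − A₀)e^(−Δt/τ) with all three
parameters free (whether A∞ should be fixed at 1 is not determinable from
the published analyses; leaving it free is conservative).  `nls` with a
scale offset handles the zero-residual noiseless case; a τ-grid/profile
fallback with golden-section refinement covers pathological starts.

**Group comparison.**  Thin wrappers over the exact/normal-approximation
Wilcoxon rank-sum and Kruskal–Wallis tests, matching an enumeration oracle
on small disjoint groups (p = 2/C(10,5)).

## The stated world of the validation suite

The generator's defaults are the published parameter values of the
synapse phenotypes they emulate, fixed before the acceptance suite was
frozen:

| preset | N | Pr | TCR latency/FWHM (ms) | replenish (quanta/ms) |
|---|---|---|---|---|
| `wild_type` | 44 | 0.21 | 0.65 / 0.35 | 0.425 |
| `syt2_rescue` | 44 | 0.20 | 1.17 / 0.78 | 0.49 |
| `syt1_rescue` | 38 | 0.22 | 1.64 / 2.00 | 0.18 |
| `syt2_rescue_pool` | 44 | 0.20 | 1.17 / 0.78 | 0.0204 |
| `syt1_rescue_pool` | 38 | 0.22 | 1.64 / 2.00 | 0.0077 |

Two replenishment regimes exist because the constant-rate single-pool
model cannot reproduce, with one rate, both the published steady-state
depression (IPSC₅₀/IPSC₁ ≈ 0.56, requiring r ≈ 0.49 via
r = ratio·N·Pr/Δt) and unbiased back-extrapolation (requiring b ≪ 1).  The
`*_rescue` presets reproduce the depression profile; the `*_pool` presets
use the post-train refill readout RRP/τ_recovery (44.3/2170 ms ≈ 0.02
quanta/ms) and are the regime in which pool-parameter recovery is tested.
The published within-train refill value itself appears to be a per-stimulus
quantity mislabeled per ms (slope × quantal content ≈ 3.9 per stimulus),
and is not used as a generator parameter.

Mini validation runs at 3.75 Hz, 100 pA amplitude, noise SD 8 pA
(SNR 12.5, within the stated SNR ≥ 10), 10 kHz bandwidth, 100 s sweeps.
Latency-jitter validation uses 100 single-quantum trials with Gaussian
jitter SD 0.15 ms at SNR 20.

**What green tests establish — and what they do not.**  Parameter recovery
on this generator shows the estimators are correct *for data satisfying
the model's assumptions*: uniform Pr, stationary quantal size, no
receptor saturation/desensitization, no series-resistance artifacts, no
electrotonic filtering gradients, Gaussian band-limited noise.  Real
recordings violate several of these (the experimental literature controls
them pharmacologically or by recording quality criteria); the suite
quantifies the estimator biases that follow from the model itself
(back-extrapolation under replenishment, (1 − Pr) fluctuation-slope bias,
overlap-merging in detection) but cannot certify robustness to
out-of-model physiology.

## Numerical choices

* Sub-sample event placement and trace alignment use linear interpolation;
  the worst-case kernel error is bounded by the kernel's curvature over
  half a sample and is asserted in the renderer tests.
* Peak times feeding latency/delay measures are refined with a 3-point
  parabola.
* Degenerate inputs fail loudly: zero-variance sweeps warn and return
  empty tables; flat decay/recovery data raise fit-failure errors;
  non-positive cumulative intercepts flag the pool estimate invalid
  rather than clipping it.
* Containers are plain text: a directory with `sweeps.csv` (%.17g, so
  doubles round-trip bit-exactly), `ap_times.json`, `meta.json`; a
  single-file CSV fallback embeds metadata in `#` header lines.  Configs
  are JSON.  One global seed expands into counter-based per-stage,
  per-sweep substreams, so enlarging an ensemble never perturbs earlier
  draws, and fixed-seed runs are bit-reproducible.

## Known limitations

* Single homogeneous pool, constant-rate replenishment — no facilitation,
  no calcium dependence, no Pr heterogeneity.
* The detector cannot split events closer than roughly one template
  length; merged events bias rate estimates down by ~5% at 3.75 Hz.
* Back-extrapolation and fluctuation-analysis biases are inherent to the
  published estimators and are reported, not corrected.
* The deconvolution regularization is a reconstruction of an unspecified
  original; only its ground-truth recovery behaviour is guaranteed.
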