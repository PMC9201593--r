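---
title: "motorconn: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motorconn: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside the package: what each stage
estimates, under which assumptions, which parameters matter and why
their defaults are what they are, what the synthetic generators do and
do not emulate, and where a genuinely open design question was settled
by a package-level decision.

## 1. Signal model and preprocessing

A `recording` is a channels × samples matrix of extracellular voltage
with a sampling rate and per-channel (area, layer) labels. Local field
potentials are analysed below ~250 Hz; spiking activity between 0.3 and
3 kHz; both views come from the same wide-band trace by zero-phase
Butterworth filtering.

**Zero phase everywhere.** All IIR filters (Butterworth band limits,
biquad line-noise notches, anti-alias low-passes) are applied
forward–backward, doubling the effective order and cancelling phase.
The directed-connectivity stage estimates lags of tens of
milliseconds; a causal filter's group delay would contaminate exactly
the quantity of interest, so zero-phase filtering is not optional here.

Numerical details that matter in practice:

* Band-pass filters are applied as a high-pass/low-pass cascade. A
  joint band-pass design whose lower edge is a tiny fraction of the
  Nyquist rate (0.1 Hz at 20 kHz is a normalized edge of 1e-5) has
  polynomial coefficients beyond double precision and diverges.
* For high-pass edges below a normalized frequency of 2e-5 the
  order-2 prototype is used (still effective order 4 after the
  forward–backward pass); the order-4 design loses precision there.
  The channel mean (DC, always in the stop band) is subtracted before
  high-pass filtering, which suppresses multi-second start-up
  transients at no cost.
* Notches are single biquads with a 2-Hz default width: ≥ 20 dB at the
  line frequency, < 1 dB five hertz away.
* `downsample()` decimates by integer factors (cascaded stages of ≤ 13
  so the per-stage anti-alias cutoff, 0.49 of the new Nyquist at order
  8, stays numerically comfortable). Rational non-integer ratios are
  rejected with an informative error; every rate pair the pipeline
  uses (20 000 → 200, 5000 → 200, 1000 → 200 Hz) is an integer factor.

Epochs are non-overlapping and contiguous from the start of the
recording; an epoch that touches a single masked (artifact) sample is
dropped entirely. Artifact identification itself is the caller's
responsibility (a per-sample logical mask): independent-component
cleaning of raw EEG is deliberately out of scope, so conservative
epoch dropping replaces interpolation. Filtering is applied before
masking and epoching.

## 2. Multitaper power and frequency bands

Power spectra use DPSS (Slepian) tapers computed from the standard
symmetric tridiagonal eigenproblem, averaged over tapers, segments and
epochs. Defaults: 50-ms segments, time–bandwidth product NW = 2 with
3 tapers, 0.25-Hz output grid obtained by zero-padding each segment to
`fs / 0.25` points. Short segments trade frequency resolution
(bandwidth NW/T = 40 Hz at 50 ms) for many averages on nonstationary
data; analyses that need to resolve low-frequency shape (the 1/f slope,
narrow lines near band edges) should pass `segment_s = 1` or longer,
as the examples do. The estimator satisfies Parseval — PSD integrated
over [0, Nyquist] equals the signal variance — which the tests verify
to within 5% on white noise.

**Band tables.** Printed integer band edges are interpreted half-open:
band (low, high) covers `[low, high + 1)` Hz, so adjacent printed bands
(delta 0–3, theta 4–7, …) tile without overlap while the deliberate
gap around 50 Hz line noise (low gamma ends at 49, medium gamma starts
at 51) survives. For *bin membership in averages* the upper bound is
`high + step` with `step` the grid step (capped by the lookup bound):
on a 0.25-Hz grid low gamma therefore ends at 49.25 Hz, which keeps a
50-Hz residual line out of both flanking bands. Mouse and human
presets differ exactly in their printed definitions (mouse beta 16–31,
human beta 14–30 with a single gamma 31–100); the delta band starts at
0.1 Hz, the effective lower edge after the standard high-pass.

## 3. Coherence and the block-shuffle surrogate

Magnitude-squared coherence uses Welch averaging: Hann-windowed 2-s
segments with 50% overlap by default, giving the conventional 0.5-Hz
grid. Coherence estimated from K independent segments has an
`O(1/K)` positive bias on independent signals — visible in the tests —
which is precisely why significance comes from a surrogate rather than
a parametric null.

The surrogate permutes the order of 500-ms blocks of **one** channel
(permuting both with the same permutation preserves alignment classes;
permuting both independently is equivalent but slower), recomputes the
coherence, and repeats `n_perm = 100` times. Block permutation keeps
every sample, hence the channel's mean, variance and amplitude
histogram, while destroying cross-channel temporal structure. A
frequency bin (or band mean) is significant when the observed value
exceeds the per-frequency `1 − α` surrogate quantile (α = 0.05
default, configurable; `α ≥ 1` marks everything significant by
convention). Whether the threshold should be per-frequency or pooled
across a band is genuinely open; the package computes both, and the
band-level decision compares band means against the null distribution
of band means.

## 4. Time-resolved partial directed coherence

From VAR coefficients `A_1..A_p` fitted at rate `fs`, with
`Ā(f) = I − Σ_r A_r e^{−i2πfr/fs}`, the partial directed coherence is

```
PDC(i←j, f) = |Ā_ij(f)| / sqrt(Σ_m |Ā_mj(f)|^2)
```

— column-normalized so that `Σ_i PDC²(i←j, f) = 1` exactly, a property
the tests assert to 1e-12 and cross-check against a brute-force
implementation to 1e-10.

**Time-varying estimator.** The coefficients are re-estimated by
ordinary least squares in sliding windows (default 2-s windows, 0.5-s
step) and the PDC is averaged over windows and band bins. A dual
extended Kalman filter is the classical alternative for time-resolved
estimation; windowed OLS was chosen because it is deterministic,
directly testable against the stationary closed form, and sufficient
for resting-state (quasi-stationary) data. The window solver uses the
normal equations when well-conditioned and falls back to truncated-SVD
least squares: strongly low-pass content and notch nulls make lagged
copies of the signal nearly collinear, and inverting those directions
would amplify noise; dropping them gives the minimum-norm solution.
Only exact numerical singularity is an error (naming the window).
Unstable windows (companion spectral radius ≥ 1) produce a warning,
not an error.

**Estimator bias and window length.** PDC is a nonlinear function of
the coefficients, so per-window estimation noise leaves a small
positive bias on null influences that shrinks with window *length*,
not with window *count*. The oracle-equivalence test therefore uses
10-s windows on 5 minutes of stationary VAR data (bias < 0.03); for
nonstationary use the 2-s default trades a little of this bias for
time resolution.

**Model order** is selected once on the full series by AIC over
p = 1…20 (ties to the smaller order) and then held fixed across
windows and surrogates. On 1/f-background data the criterion
typically picks large orders (15–20): long-memory background genuinely
needs them, and they also cover coupling delays up to 100 ms at
200 Hz.

**Channel selection.** One channel per (area, layer) enters the TPDC,
chosen as the argmax of theta-band (4–7 Hz) mean power within the
group; exact ties resolve to the channel listed first in the channel
table.

**Time-reversal significance.** For each unordered pair and band, the
asymmetry `Δ = TPDC(a→b) − TPDC(b→a)` is computed on the forward data,
on the time-reversed data, and on `n_surr = 19` surrogates in which
each channel is independently block-shuffled (500-ms blocks). An edge
is significant iff `|Δ|` exceeds the `1 − α` surrogate quantile *and*
Δ changes sign under time reversal. The sign-flip requirement is what
makes the test robust to volume conduction: an instantaneous mixture
is symmetric under time reversal, so its (noise-level) asymmetries do
not flip systematically and are rejected. The cited methodology
specifies the time-reversal idea but not a decision rule; the
threshold-plus-sign-flip rule above is this package's concrete
instantiation, and its calibration (false-positive rate ≤ α + 0.03
under pure mixing; ≥ 90% recovery of planted couplings at lags of
1–20 samples) is enforced by the acceptance tests.

## 5. Spike sorting

Detection: local minima below −5 robust SDs with a 1-ms dead time;
troughs beyond 30 SDs are artifacts and are excluded (a hard
guarantee — no retained event exceeds the bound). The noise scale is
`median(|x|)/0.6745`, which a spike train does not inflate; the
literal raw SD is available via `noise_sd = "raw"`. Waveforms span
−0.5…+3 ms around the trough (the trough at the −0.5-ms offset), with
the trough position refined on a dense cubic-spline grid and the
waveform resampled on the aligned grid. This sub-sample alignment is
load-bearing: ±1 sample of sampling jitter otherwise splits one unit
into several feature-space clouds, and a 3-point parabolic refinement
is noise-dominated on broad flat troughs.

Features: 4-level orthonormal Haar transform of each waveform;
coefficients ranked by the Kolmogorov–Smirnov deviation of their
across-event distribution from a Gaussian with matched moments; top 10
kept. Multimodal coefficients — the ones that separate units — score
highest; constant coefficients score 0 and are never selected.

Clustering is super-paramagnetic: a q = 20 Potts model on the
11-nearest-neighbour graph, simulated by Swendsen–Wang sweeps across a
temperature grid (0–0.2 in steps of 0.005; the informative window
between cluster splitting and erosion can be narrower than 0.01), with
spin–spin pair correlations > 0.5 defining clusters. Three decisions
around the raw Potts output:

* **Working temperature** — the lowest temperature attaining the
  maximal number of clusters with ≥ `min_cluster` (20) members: the
  entry into the most resolved super-paramagnetic plateau. Selecting
  instead the *highest* temperature at which a large cluster survives
  rides the erosion edge of the phase diagram, where cores shed most
  of their members before dissolving into dust.
* **Valley-statistic merge and split** — two clusters are fragments of
  one unit iff the pooled kernel density along their centroid-difference
  axis shows no valley between the projected modes (density ratio
  midpoint/modes > 0.5); conversely a cluster whose best 2-means
  bipartition reveals a deep valley (< 0.5) is split, which resolves
  two touching units the Potts dynamics cannot separate. On labelled
  fixtures genuine unit pairs measure ≤ ~0.25 and cuts through a
  single cloud ≥ ~0.85, so the 0.5 threshold sits in a wide margin.
* **Force membership** — events outside every core are attached to the
  nearest core centroid when they fall within that core's own spread
  (99th-percentile member distance × 1.1), the standard final step of
  template sorters; events beyond every gate stay unassigned, and
  assigned + unassigned always equals detected.

Quality screening drops units with > 2% inter-spike-interval
violations of a 1-ms refractory period, or a > 30% change in mean
trough amplitude between the first and second half of the recording
(instability/drift). These two rules are explicit substitutes for
tool-specific quality metrics that are not reproducible from their
description.

## 6. Path (mediation) models

The feature-level model is an observed-variable recursive path
analysis: input → each mediator, each mediator → output, plus the
direct input → output path (3 paths with one mediator, 5 with two).
All variables here are observed summaries (directed influence,
coherence, band power, unit rate), so latent-variable machinery is
unnecessary. Disturbances are independent Gaussians by default;
`free_mediator_cov = TRUE` frees the mediator residual covariance
(making the two-mediator model saturated).

Fitting minimizes the ML discrepancy
`F = log|Σ(θ)| + tr(S Σ(θ)^{-1}) − log|S| − k` with
`Σ(θ) = (I−B)^{-1} Ψ (I−B)^{-T}`, variances parameterized on the log
scale, started from equation-wise OLS (which for a recursive model
with diagonal Ψ is itself the ML estimator — and serves as an
independent oracle in the tests), and polished by BFGS;
`χ² = (n−1)·F` at the optimum. Standard errors come from the observed
information; standardized coefficients from the model-implied
variances, and they are invariant to positive column rescaling to
numerical precision. `RMSEA = sqrt(max(0, (χ²−df)/(df(n−1))))` (0 for
saturated models) and `AIC = χ² + 2q` (the structural-modeling
convention; the raw `−2logL + 2q` variant is reported alongside). The
"invariance under constant scaling" criterion is implemented as the
maximum absolute change in standardized coefficients under random
positive rescaling of the columns — a substitute definition, labelled
as such, since no standard published formula exists.

One calibration fact worth knowing: the five-path two-mediator model
on four observed variables has df = 1, so under the true model the
sample RMSEA at n = 500 falls below the conventional 0.05 cutoff with
probability ≈ `P(χ²₁ < 2.25) ≈ 0.87` — a per-dataset coin with an
87% success rate, not a certainty. The test suite states this check
at the conventional rate and it can land either side of 90% over 20
replicates.

Group comparisons are Welch (unequal-variance) two-sample t-tests with
Bonferroni correction; the family size defaults to the number of
comparisons actually made and can be set to match a wider family
(e.g., 7 bands, 9 layer pairs).

## 7. Synthetic data: what it does and does not emulate

The generators provide every input with known ground truth:

* **Band-coupled field potentials** — unit-SD 1/f^α background per
  channel (spectral shaping of white noise; exact average slope
  control), plus, per coupling, a band-limited oscillation added to
  the source and a delayed, gain-scaled copy added to the target. The
  band-pass is applied causally (single pass) so the injected
  influence is strictly causal on top of the explicit lag. Optional
  full-rank instantaneous mixing emulates volume conduction.
* **VAR processes** — exact coefficient ground truth for the directed
  estimators; stationary covariance available in closed form
  (companion-form Lyapunov solution) for oracle checks.
* **Spiking traces** — Gaussian noise with biphasic negative-dominant
  templates (default width 1.5 ms, matching the −0.5/+3-ms extraction
  window) inserted at known times.
* **Mediation tables** — linear structural equations with independent
  Gaussian disturbances; by default disturbance variances are chosen
  so every variable has unit population variance, making the supplied
  path coefficients the standardized truth. The ML fit is then
  correctly specified. Study-scale defaults used in the acceptance
  checks (paths 0.7/0.6/0.5/0.4 with a 0.2 direct effect, n = 500)
  mirror the strong standardized associations reported for this kind
  of cortical circuit data.

Deliberate non-goals: no conductance-based neuron models, no forward
EEG head-model simulation, no source reconstruction. Passing tests on
these generators demonstrates estimator correctness and calibration
under the stated statistical assumptions (Gaussian 1/f-plus-oscillation
backgrounds, linear mixing, stationary couplings); they do not certify
behaviour under nonstationary artifacts, non-Gaussian noise, or
electrode drift beyond the drift screen in the spike module.
Amplitude distributions of real recordings are not characterized by
the source material; generator defaults are stated choices, not
inferences.

## 8. Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is bit-reproducible
given one; `run_pipeline()` derives per-subject, per-stage seeds from a
single master seed and writes a manifest with md5 hashes of every
output file, so two runs with the same config and seed are verifiably
identical.

The test and acceptance workloads use desk-scale problem sizes chosen
to keep Monte-Carlo error comfortably inside the asserted tolerances:
45–60-s two-channel recordings at 200–1000 Hz for connectivity checks
(20 seeds for direction recovery across lags 1–20; 50 seeds for
volume-conduction and surrogate calibration), 30-s 20-kHz traces with
three planted templates at SNR 8 (10 seeds) for sorting, and n = 500
feature tables (20 recovery replicates, 200 calibration replicates)
for the path models. `scripts/acceptance.R` re-runs all of it from a
single `--seed` and writes the measured quantities as JSON.

## 9. Known limitations

* Non-integer resampling ratios are not supported (never needed by the
  standard rate chain).
* EDF input is not implemented; recordings enter via the HDF5 layout
  or delimited text.
* The windowed-OLS TPDC assumes quasi-stationarity within windows; an
  adaptive (Kalman/RLS) estimator is a natural extension point with
  the same output contract.
* Spike sorting is single-channel; no template matching or overlap
  decomposition, no tetrode-style cross-channel sorting.
* The surrogate and TRT decision rules are calibrated for two-channel
  analyses; with many channels the per-pair tests are not corrected
  for multiplicity (the group-level machinery in `pairwise_band_tests`
  is the place to do that).
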