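---
title: "Occlusal signal analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusal signal analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlusignal)
```

This vignette is the package's own account of the science it implements:
the signal model behind the synthetic generator, the three conditioning
steps and their numerical realisation, the feature and embedding
definitions, the classification protocol, and the design choices made
where the problem left the design genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement and its signal model

An instrumented dental aligner carries one piezoelectric pressure sensor
per tooth site — eight per jaw: left/right central incisors (LCI, RCI),
first premolars (LFP, RFP), first molars (LFM, RFM) and second molars
(LSM, RSM) — sampled at up to 50 Hz. A bite is a contact–separation
cycle: compression of the sensor transfers charge one way and release
transfers it back, so one cycle produces a biphasic voltage pulse whose
positive and negative lobes enclose (nearly) equal areas. The package
models a cycle as a positive half-sine of duration 0.15 s followed by a
negative half-sine of 0.25 s whose amplitude is set by that charge
balance (`pulse_shape()`); only the sign pattern and approximate
durations are physically constrained, not the exact waveform.

What distinguishes occlusion classes is not the pulse shape but the
*relative pulse amplitude across sites*. `class_profile()` encodes each
class as a site-gain map:

* **An I** (and **CO**): all sixteen gains 1 — the reference pattern.
* **An II**: mandibular second molars and maxillary incisors at 0.4.
* **An III**: the mirror image (maxillary second molars, mandibular
  incisors at 0.4).
* **OB** (open bite): incisors at 0.3 in *both* jaws, posterior teeth
  unchanged.
* **MD** (mandibular deviation): right-side gains 0.5 (a mirrored variant
  is chosen by seed parity at simulation time, keeping `class_profile()`
  itself deterministic).
* **LB / TS** (lip biting / thumb sucking): molars at 0.2; premolars 0.6
  for LB versus 0.2 for TS. The direction — anterior activity with molars
  silent — is clinically motivated; the premolar split between the two
  habits is an assumption this package makes so the four-habit task is
  well posed, and is flagged as such.
* **GT** (teeth grinding): posterior sites active in alternating 2 s
  left/right blocks (the block exceeds the 1 s analysis window, so
  windows see one-sided activity), incisors at 0.1.

The gain *directions* follow the clinical signatures; the magnitudes
(0.4, 0.3, 0.5, …) are package defaults chosen once to be clearly
resolvable at the default noise level without being trivially separable.

A simulated recording (`simulate_recording()`) is then

> observed = A · clean + drift + noise,

where each row of `clean` is an independently jittered pulse train scaled
by the site gain, `A` is a crosstalk matrix with unit diagonal and random
off-diagonal entries bounded by the crosstalk level (redrawn if its
condition number reaches 50), the drift is a 0.3 Hz sinusoid of 0.5 V
with a random phase per channel (slow charge accumulation motivates a
sub-1 Hz term; a single sinusoid plus optional ramp is the simplest model
with the right band), and the noise is white Gaussian at 20 dB SNR
against the mean clean channel power — so silent channels still carry
sensor noise, as real electronics do.

**Pulse timing.** Cycles are laid down at 1 Hz (a realistic chewing/bite
rate; the true rates are not constrained by any published value) with
each cycle start drawn uniformly within its full period
(`pulse_jitter = 1`). This choice matters: with per-cycle uniform-circular
lags, the relative phase of two channels' trains is redrawn every cycle,
so their empirical correlation vanishes as cycle count grows and the
channels satisfy the independence assumption blind source separation
requires. A periodic or weakly jittered train keeps a frozen relative
phase and a per-recording correlation of order 0.1–0.4, which no ICA
implementation can undo. The cost of full jitter is a few percent of
pulse energy below 1 Hz (random timing has low-frequency power), which
the drift filter removes along with the drift; the canonical periodic
train (`jitter = 0`) keeps all its power at harmonics of the pulse rate.

**What the generator does not emulate.** Real recordings contain
sensor-specific gain drift, bite-to-bite force variability, subject
motion artifacts, unequal per-class prevalence and hardware quantisation.
Passing tests on synthetic data therefore demonstrate that the *pipeline*
recovers the class structure it was told exists — they validate the
algorithms, not the clinical effect sizes, and reported accuracies are
not comparable to accuracies on patient data.

## 2. Conditioning

The conditioning order is fixed: low-pass, then drift removal, then ICA.
Each step preserves sample count and sampling rate.

**Low-pass (20 Hz).** The acquisition front end band-limits at 20 Hz in
hardware; the package applies the equivalent in software so synthetic
data see the same response. The filter is an order-8 type-II Chebyshev
low-pass (monotone passband, 40 dB stopband from 1.25 × cutoff) run
forward and backward, so the response is zero-phase and attenuation
doubles. When 1.25 × cutoff is not representable below Nyquist (e.g.
20 Hz at fs = 50), an order-8 Butterworth at the cutoff is used instead —
only the passband contract applies there. Two numerical details carry
the correctness burden: each pass starts from the steady state of a
constant input equal to the first sample (so DC passes to machine
precision), and edges are extended by linear prediction (a Burg AR(≤12)
fit continued beyond both ends) before filtering. Mirror or
point-reflected extensions inject genuine low-frequency energy at the
pad junction — a stopband tone leaks in at the percent level through any
such pad, as it does in widely used zero-phase implementations — whereas
the AR continuation keeps oscillatory signals oscillating and drops that
leakage below 10⁻⁵.

**Drift removal (< 1 Hz).** Per channel, the DFT is taken, every bin with
|f| strictly below 1 Hz (DC included) is zeroed, and the real inverse
transform returned. "Below 1 Hz" is read literally: a bin at exactly
1 Hz is kept. The operation is a projection, hence idempotent and
energy-non-increasing, and it forces each channel's mean to zero. It
requires at least 2 s of data per Hz of cutoff so the removable band
spans whole bins.

**FastICA.** Crosstalk mixes the channels; `fastica_unmix()` centres the
data, whitens via the eigendecomposition of the channel covariance
(rejecting rank-deficient input), and runs the symmetric fixed-point
iteration with the log-cosh (tanh, a = 1) contrast from a seeded random
orthogonal start, with symmetric decorrelation after every update
(tolerance 1e-6 on the rotation change, at most 500 iterations;
non-convergence is reported in the result, not an error — for Gaussian
sources the rotation is unidentifiable and the caller decides).
Separation quality is scored by the Amari index of
`unmixing %*% true_mixing`, normalised to [0, n−1] and zero exactly on
scaled permutations.

ICA output is ordered arbitrarily, sign-ambiguous and unit-variance.
`align_sources()` resolves all three against a reference recording
(the pre-ICA conditioned channels): greedy one-to-one assignment by
descending |correlation|, sign flip to positive correlation, and — by
default — a least-squares rescaling of each source onto its reference
channel. The rescaling goes beyond a bare permutation-and-sign fix on
purpose: the diagnostic signal of this application *is* the per-site
amplitude, and unit-variance sources would erase it. With near-diagonal
mixing the regression restores each site's physical scale while keeping
the crosstalk suppression ICA provided.

**Study size for the separation experiment.** FastICA's estimation error
scales as the inverse square root of the number of statistically
independent samples. A pulse train at 1 Hz has an autocorrelation time of
one cycle, so a recording contributes roughly one independent event per
second regardless of fs. At ~5,000 samples (100 s) the estimator variance
alone leaves the Amari index near 0.1 — a figure this package's
implementation shares to three decimals with an independent FastICA
implementation on identical data — so the separation study uses
30-minute continuous monitoring recordings (90,000 samples at 50 Hz),
where the index falls to ~0.03 and 0.3-level crosstalk is recovered to
Amari < 0.05 in 10/10 seeds. Thirty minutes is a realistic session for a
wearable monitor; per-recording ICA inside the classification pipeline
(10 s recordings) is not asked to meet that bar — there it functions as
crosstalk suppression ahead of alignment, at the default crosstalk level
of 0.15.

## 3. Features

Conditioned recordings are cut into contiguous, non-overlapping 1 s
windows ("sampling interval of 1 s" is read as stride = window; trailing
remainders are dropped). A window is valid when its largest absolute
amplitude over all channels reaches 3 × the noise floor, estimated as
1.4826 × the median absolute deviation of the conditioned recording (a
robust Gaussian-consistent scale that ignores the sparse pulses). The
boundary is inclusive with a 1e-12 relative guard.

Each channel of a valid window yields six features: maximum; minimum;
peak-to-valley interval (time between the global maximum and minimum,
ties to the earliest index, with a 1e-9 relative tolerance so
analytically equal peaks are not ranked by floating-point noise); zero
crossings (strict sign changes between consecutive nonzero samples —
exact zeros are ignored); inflection points (sign changes of the second
difference, hence the 3-sample minimum); and the absolute square value,
interpreted as the signal energy Σxᵢ² — the natural scalar reading, and
stated prominently because the term alone does not pin the definition
down. Columns are ordered site-major, feature-minor
(`MAX_LCI_max … MAN_RSM_abs2`).

Two aggregations exist because the right row unit is application-
dependent: `per_window` (one row per valid window) and
`per_recording_mean` (features averaged over a recording's valid
windows). The classification tasks default to `per_recording_mean` — one
articulator bite sequence, one row — which also removes any risk of
windows from one recording straddling the train/test split.
Normalisation is a z-score with population (divisor-n) statistics
computed on training rows only and frozen for held-out data;
zero-variance columns get scale 1 with a warning.

## 4. Embeddings

**PCA** is implemented from its definition: column means, divisor-*n*
covariance U = (1/n) Σ φᵢφᵢᵀ (the divisor is n, not n−1, and the
projected column variances equal the eigenvalues under that same
divisor), eigenpairs sorted by descending λ, a deterministic sign
convention (each eigenvector's largest-magnitude entry is positive), and
projection yᵢ = Wᵀ(xᵢ − x̄). `k` is truncated to the number of strictly
positive eigenvalues with a warning. The test suite checks the full
eigenstructure against an independent SVD oracle at 1e-8.

**t-SNE** follows the standard formulation: Gaussian conditional
affinities whose per-point bandwidth σᵢ is found by bisection on the
precision so that 2^(entropy) matches the target perplexity within 1e-3
(≤ 64 iterations, σ bracketed in [1e-20, 1e20]; the bracket expands
geometrically before halving). Where the target is unachievable — two or
more exactly equidistant nearest neighbours bound the entropy from below
— the bisection returns the closest achievable distribution, which for
the fully symmetric case is the uniform conditional. Affinities are
symmetrised as pᵢⱼ = (p_{j|i} + p_{i|j})/2N; coincident points are
rejected with the offending index. The embedding minimises
C = KL(P‖Q) over Student-t similarities by gradient descent with early
exaggeration (P × 12 for the first 250 iterations) and momentum
0.5 → 0.8 after iteration 250 — both adopted from standard practice,
since only "gradient descent" is prescribed — from a seeded N(0, 1e-4)
start, recentring every step. The cost trace is always computed against
the un-exaggerated P; perplexity 30 and 3 output dimensions are the
defaults (hyperparameters are otherwise unconstrained, so they are
ours). A non-finite cost aborts with the iteration index and
learning-rate guidance.

Silhouette widths (plain Euclidean, computed in-package) quantify class
separation in embedded views; on the synthetic malocclusion task the
combined 16-site features separate the five classes better than either
jaw alone, in embedding silhouette as in classifier accuracy.

## 5. Classification protocol

`balanced_split()` first downsamples every class (seeded, without
replacement) to the minimum class count — the simplest mechanism that
guarantees "equal class representation" — then splits each class
80:20 (`round(0.8 m)` train, at least one test row). Normalisation
statistics and downsampling use training rows only; test rows never
touch fitting.

The seven models run with fixed, seeded settings: XGBoost
(`multi:softprob`, 300 rounds, depth 6, η 0.3, single thread), RBF-kernel
SVM with probability estimates, random forest (500 probability trees), a
one-hidden-layer "BP" softmax network of 64 units and a two-hidden-layer
64/32 MLP — both trained by the package's full-batch Adam backprop
routine (ReLU hidden layers, He initialisation, 400 epochs, learning
rate 5e-3), which exists because no installed library offers a seeded
two-hidden-layer perceptron and a quasi-Newton single-layer fit is
quadratic in the weight count at this feature dimension — 5-nearest-
neighbour voting with distance-based per-class vote fractions, and a
CART decision tree. A model that fails to fit is recorded and skipped;
the suite continues.

Reports carry per-model accuracy, the confusion matrix (rows = truth),
per-class precision/recall/F1 (0/0 conventions resolved to 0),
macro-F1, and one-vs-rest AUC computed as the Mann–Whitney rank
statistic with tied ranks averaged, macro-averaged across classes.

Per-tooth-site importance is permutation importance: shuffle one feature
column at a time in the held-out rows (seeded, `n_repeats` = 20 by
default), record the accuracy drop, and sum the drops over the six
features of each site; per-class values use one-vs-rest accuracy.
Permutation importance replaces Shapley-value attribution deliberately —
it is model-agnostic, dependency-light and directly interpretable as
held-out accuracy loss — with the caveat (documented on the function)
that perfectly correlated columns share credit.

## 6. Study sizes and reproducibility

The packaged study conditions, used by the test suite and
`scripts/acceptance.R`:

* Malocclusion task: 100 recordings per class × 5 classes, both jaws,
  10 s recordings at 50 Hz, SNR 20 dB, drift 0.5 V at 0.3 Hz, crosstalk
  0.15, full conditioning with per-recording ICA; held-out XGBoost
  accuracy summarised as the median over 10 split/training seeds on one
  simulated dataset (the split and model seed is the only randomness the
  evaluated quantity depends on once the study data exist), reported for
  combined, maxilla-only and mandible-only feature views.
* Habit task: 50 recordings per class × 4 classes (CO/LB/TS/GT),
  mandible only — matching the 8-site single-jaw habit experiment —
  same summary, plus the silhouette of the 3-D PCA of the habit
  features.
* Separation experiment: 8 channels, crosstalk 0.3, 30-minute
  recordings, 10 simulation seeds.
* Embedding checks: 60 points in three 10-D blobs (t-SNE), 50 × 6
  random tables (PCA oracle).

Every stochastic step — simulation, mixing draws, ICA initialisation,
splits, model fits, permutation shuffles — consumes a sub-seed derived
deterministically from one master seed, so identical configurations
reproduce identical artifacts byte for byte (`run_pipeline()` writes a
manifest recording the configuration and per-stage counts alongside the
outputs).

## 7. Known limitations

* The generator's gain magnitudes, pulse rate and variance structure are
  package choices, not measured clinical values; accuracies on synthetic
  data bound what the pipeline can recover under its own assumptions,
  nothing more.
* Per-recording ICA on 10 s recordings estimates a 16 × 16 unmixing from
  500 samples; it suppresses crosstalk but should not be expected to
  reach the separation quality of the 30-minute experiment.
* The LB/TS premolar distinction is an assumption; with it removed the
  two habits are nearly indistinguishable by construction.
* t-SNE is the exact O(N²) formulation; embedding thousands of windows
  will be slow (no tree-based approximation is provided).
* The analysis assumes one channel per tooth site with a total, injective
  channel map; partially instrumented arches are not modelled.
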