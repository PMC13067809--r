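---
title: "Methods: signal processing, heartbeat clustering and dielectric analysis for electrode benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing, heartbeat clustering and dielectric analysis for electrode benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ElectrodeBench)
```

ElectrodeBench implements the computational pipeline used to benchmark
skin electrodes across electrophysiological modalities. This vignette
documents the models, the parameters that matter, the numerical choices,
and what the synthetic validation can and cannot show.

## The synthetic cohort model

### Heartbeat morphology

Each participant is a `BeatTemplate`: five Gaussian deflections (P, Q, R,
S, T), each with amplitude (mV), center (s, relative to the R apex) and
width (s), plus RR-interval mean and SD. A Gaussian-wave beat model is the
simplest parameterization that exposes exactly the landmarks the analysis
measures (peak-to-peak, P and T amplitudes, QRS timing); it makes the
generator's ground truth directly comparable to what the morphology module
estimates.

Cohort variability comes from `cohortPriors()`: normal distributions
truncated at ±2 SD (so templates stay physiological and the truncation
leaves the mean essentially unbiased — the Monte-Carlo prior-recovery test
relies on this). The default spreads reflect what is seen across resting
adults: R amplitude 1.0 ± 0.2 mV, T amplitude 0.30 ± 0.10 mV, P center
−150 ± 20 ms, T center 270 ± 30 ms, RR 0.95 ± 0.04 s. Narrower priors
produce cohorts whose members are hard to tell apart at realistic noise
levels; the spreads above make participant identity recoverable from beat
shape, which is the premise of the identification task.

### Lead projection

A beat is projected onto the three chest leads by a per-wave gain matrix
rather than a per-lead scalar. This matters: every ECG wave has its own
electrical axis, so the relative wave amplitudes differ between leads —
lead II carries the largest R, lead I relatively prominent P and T with a
smaller R, lead III a small R with deep Q/S and an inverted T. A scalar
gain per lead would make leads collinear in beat space; clusters would
then differ only in norm and overlap heavily once inter-participant
amplitude spread is realistic. The per-wave defaults give the leads
distinct shapes, which is what the lead-identification task exploits.

### Noise, artifacts and the electrode transfer

`NoiseSpec` injects, per lead: sub-1 Hz sinusoidal baseline wander
(default 0.15 mV at 0.25 Hz), mains interference at 50 Hz and at the
80 Hz component observed alongside it (0.05 / 0.02 mV), white broadband
noise (0.04 mV SD), and Hann-windowed motion-artifact lumps at Poisson
times (2/min, 0.5 mV, 1.5 s) — the burst-like contamination that segment
rejection exists to catch. The 80 Hz component is injected as an
independent sinusoid, not phase-locked to 50 Hz.

`ElectrodeModel` abstracts the electrode as a single-pole low-pass at
`lpCutoff` plus gains on the noise and drift components. The presets
(hydrogel-like: 40 Hz pole, noise gain 0.7, drift gain 0.6; Ag/AgCl-like:
95 Hz pole, unit gains) encode the qualitative contrast of interest —
an interfacial capacitive filter versus a wider-band faradaic interface —
and are configuration, not measured claims. The `ideal` electrode is the
identity transfer, used by the clean-signal identities.

The generated record is mean-subtracted per lead before noise is added:
physical recorders are AC-coupled, and without this the periodic beat
train carries a DC offset that the baseline-removal stage would "remove",
spuriously failing the clean-signal identity.

## Preprocessing chains

All IIR filters are Butterworth designs applied forward–backward
(`signal::filtfilt`), i.e. zero-phase. The protocols specify cutoffs and
orders but not the phase convention; zero-phase is chosen because group
delay would bias every morphology measurement (landmark positions,
cross-correlation lags) that the beat analysis performs. Quoted
attenuations therefore refer to the squared magnitude response.

* ECG: low-pass 90 Hz (order 4) → notches 50 and 80 Hz (order 2, ±1 Hz
  half-bandwidth — "narrow-band" made concrete) → subtraction of a
  trailing ("lookback") 1 s moving average → variance-based segment
  rejection. Each step can be run in isolation (`mode = "lowpass"` etc.)
  for processed-to-raw band-power ratios.
* EOG: band-pass 0.1–15 Hz (order 4) → mean subtraction → linear detrend
  → db4 wavelet denoising at level 3 → 50 ms median filter (width rounded
  to samples, forced odd). The step order follows the protocol's
  description order.
* EMG: band-pass 20–90 Hz → 50 Hz notch → cardiac template subtraction
  (template = mean of ±0.3 s windows at the supplied R times; per-beat
  least-squares scale; skipped with a warning below 3 beats) → db4
  wavelet thresholding.
* EEG: linear detrend → low-pass 49 Hz. The low-pass order (4) matches
  the ECG chain's convention; only the cutoff is protocol-specified.

Wavelet denoising uses an orthonormal periodic db4 transform with
soft thresholding at the per-level universal threshold
`sqrt(2 log n_j)·σ_j`, `σ_j` estimated by the MAD of that level's
coefficients. Orthonormality guarantees that thresholding never increases
signal energy. No wavelet library is part of the dependency set, so the
transform is implemented in the package and verified by
perfect-reconstruction and energy-conservation tests.

### Segment rejection

Non-overlapping 2 s windows are scored by the z-score of their
log-variance using the **median and MAD** across windows. A conventional
mean/SD z-score is inflated by the very burst it should detect: a single
large artifact raises the SD enough that its own z-score drops below
practical thresholds. With the robust scale, the default threshold z > 5
flags isolated bursts reliably and passes homogeneous records untouched.
Zero-variance records (MAD = 0) reject nothing. Impedance-based rejection
is applied only when an impedance series is supplied; otherwise the rule
is skipped and logged, since synthetic data carry no impedance channel.

## Heartbeat extraction

R peaks are detected with the classic Pan–Tompkins stages (band-pass
5–15 Hz, five-point derivative, squaring, 150 ms centered moving
integration) with adaptive signal/noise thresholds, a 200 ms refractory
period and a search-back pass for gaps longer than 1.66× the running RR
average. Two numerical details matter in practice:

* the derivative and integration are applied as centered (zero-lag)
  convolutions, so detections need no group-delay correction;
* when a candidate crosses the threshold, the largest integrated-signal
  maximum within the refractory span ahead is taken before committing —
  noise ripples on the rising QRS lobe would otherwise pre-empt the true
  apex and push the detection outside the refinement window.

Accepted detections are snapped to the largest-magnitude extremum of the
input signal within ±40 ms. Beats are then cut as 121-sample windows with
the R peak forced to the center (samples R−60…R+60; 0.605 s at 200 Hz).
Centering is our choice — the protocol fixes only the window length — and
matches the premise that morphological variability is expressed on both
sides of the R peak. Beats crossing record edges, or overlapping samples
rejected by the quality mask, are dropped *before* batching and counted.

## Identification pipeline

Per task, beats are PCA-reduced to the smallest number of components
reaching 99% cumulative variance, clustered by k-means, and mapped to
ground truth.

**k-means.** Lloyd iterations (cap 1000), 5 restarts, and the restart
whose centroid set maximizes the sum of squared pairwise centroid
distances is kept. Restarts are initialized with seeded **k-means++**
draws. We first implemented plain uniform data-point initialization and
found it converging — for some seeds in all five restarts — to a basin
that splits the largest lead cloud in two and merges two others; for some
cohorts that basin even has the lower within-cluster sum of squares, so
no selection rule among restarts can repair it. k-means++ spreads the
initial centroids across the data and is what standard k-means
implementations run by default, which is also the natural reading of a
protocol that varies "random states" between restarts.

**Munkres mapping.** The cost matrix is the negated cluster–class
co-occurrence count; the Hungarian algorithm (shortest augmenting paths
with dual potentials, O(n³)) minimizes total cost. Ties are real because
counts are integers; they are broken deterministically in favor of the
lowest cluster index by subtracting a sub-integer bias (scaled by
K − cluster index) from each cluster's best-class cell — too small ever
to overturn a strict cost difference. With more clusters than classes the
surplus clusters stay unmapped and score as errors. The implementation is
tested against exhaustive enumeration over all injective mappings for
C ≤ 6.

**Metrics.** Accuracy is A/N. Micro-F1 is computed as 2A/(N + A); note
the algebraic identity micro-F1 = 2·acc/(1 + acc), which the tests assert
on random label sets. Macro-F1 defaults to the *aggregate* form
`mean_c 2·TP_c/(N + TP_c)`, whose per-class terms use the global N in the
denominator; this is the form whose numbers the identification protocol
reports (for a single class it reduces to micro-F1, and under class
balance it collapses toward small values as C grows). A conventional
macro-F1 from per-class precision and recall is available with
`macro = "standard"`; we implement both rather than guessing intent.

**t-SNE** (exact, perplexity 30, Euclidean distances, early exaggeration,
momentum descent) is provided for visual inspection only; its O(n²)
gradient is deliberate, as embeddings are computed at modest n.

## Morphology and similarity

Peak-to-peak amplitude is max − min of the beat. P and T amplitudes are
absolute deviations from the **Q-point value** of the extremum before the
Q trough and after the S trough respectively — "distance from the Q wave"
read as an amplitude difference (a temporal reading would not be an
amplitude); magnitudes are reported so inverted waves give positive
amplitudes, and empty search segments yield `NA` with a warning rather
than a silent zero. On centroid beats, which carry no detector
annotations, Q and S are the minima within 60 ms before/after the window
center. The normalized cross-correlation is evaluated at all lags in
(−N, N) with zero padding and normalized by the two beats' energies
(scale-invariant); NRMSE divides the RMSE by the value range over the
union of both beats, with the 0/0 case of two identical constant beats
guarded to 0.

## Signal quality

SNR is the variance ratio in dB between an activity segment and a noise
reference. For ECG, noise windows are 100 ms, centered halfway between
successive R peaks — between the T and the next P, capturing the noise
floor without physiological waves. Welch PSDs use 2 s Hamming windows at
50% overlap with one-sided density scaling (integral = mean square;
Parseval is asserted to 1% on deterministic signals). Band-power ratios
default to bands {motion 0.05–0.5, LF 0.5–4, MF 4–15, HF 15–40, UHF1
40–60, UHF2 60–90 Hz} — the band names are protocol, the edges are
configuration — and use 20 s Welch windows so the sub-0.5 Hz bands are
resolved by several bins (2 s windows have 0.5 Hz resolution and leave
the lowest band empty). Time-resolved delta power uses 2 s windows at
0.5 s steps, timestamped at window centers. Scalograms use an analytic
Morlet wavelet (ω₀ = 6, 10 voices/octave, 0.5–49 Hz).

## Dielectric analysis

The relaxation time is τ = 1/(2π·f_max) with f_max located at the −Z″
maximum **on the raw frequency grid** — no interpolation, so reported
f_max values are actual measurement frequencies and the printed-value
identities hold exactly; a quadratic log-frequency refinement exists but
is off by default. A monotone −Z″ (no interior maximum) is flagged as
undefined rather than extrapolated.

Permittivity uses the parallel-plate conversion ε* = 1/(jωC₀Z*) with
C₀ = ε₀·area/thickness; tan δ = ε″/ε′ where ε′ > 0; M* = 1/ε* = jωC₀Z*.
Cell geometry defaults to a 1.7 cm diameter disc of 1.5 mm thickness
(the two printed geometry descriptions conflict; the default is
configuration and a warning is emitted when it is used implicitly).

One analytic subtlety: for the ideal single-relaxation circuit with zero
series resistance, ε′ = C_dl/C₀ is constant and ε″ ∝ 1/ω, so
tan δ = 1/(ωR_ctC_dl) is *monotone* — it has no peak. The relaxation
frequency of that circuit is marked by the −Z″ apex and equivalently by
the modulus-loss peak M″, both at exactly f = 1/(2πR_ctC_dl); the
package's consistency test therefore compares those two markers, not a
tan δ peak.

Replicate spectra (triplicate measurements are typical) are combined
pointwise into mean ± SD Nyquist curves, with centered moving-average
smoothing of the means (partial windows at the edges; window 1 is the
identity).

## Validation scale and what it shows

The simulation-based tests run the full pipeline on a cohort of 39
participants × 3 leads × 60 s at 200 Hz (about 5 000–7 500 beats) — large
enough for stable clustering scores while keeping the whole suite in tens
of seconds. At that scale, with default noise, lead identification
recovers the true lead for well over 80% of beats and participant
identification exceeds ten times chance on every lead; R-peak detection
holds ≥ 98% recall and precision at a 10 dB broadband-noise variance
ratio; and the relaxation time recovered from synthesized spectra is
within one grid step of the circuit's analytic value.

What passing these tests does **not** show: the synthetic cohort has no
respiratory sinus arrhythmia, no ectopy or rhythm pathology, no torso
volume-conductor model (lead projection is a gain matrix), stationary
noise statistics, and an electrode model reduced to one pole and two
gains. Published cohort-level scores from human recordings depend on the
recordings themselves and are not reproduced here; the package reproduces
the *procedures* and the *identities* among reported metrics, and
validates parameter recovery under its own known ground truth.

## Session info

```{r}
sessionInfo()
```
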