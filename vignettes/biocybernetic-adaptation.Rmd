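---
title: "Methods: psychophysiological features and biocybernetic adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychophysiological features and biocybernetic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocyloop)
```

## The problem

Adaptive training simulators close a loop around the trainee: measure
physiology, infer the psychophysiological state, and modulate task
difficulty toward a trainer-specified target state. For marksmanship
training the target state is commonly described as a heart rate of
100–115 BPM — aroused enough for fast cognitive responses, calm enough
for fine motor control — with frontal theta standing in for sustained
concentration. This package implements that loop end to end against a
simulated trainee, together with the feature pipelines and statistics
needed to characterise a cohort.

Because no raw cohort recordings are publicly available, everything
data-like in this package is synthetic and clearly labelled as such.
The synthetic generators are first-class, tested code: their role is to
make the pipeline's claims *checkable* (analytically forced statistics,
parameter recovery, controller convergence), not to imitate any
particular dataset.

## Synthetic physiology

### RR intervals: the IPFM model

`generate_rri()` uses integral pulse frequency modulation: a beat is
emitted whenever the integral of the instantaneous beat rate

$$m(t) = \frac{\mathrm{hr}}{60}\left(1 + a_{LF}\sin(2\pi\,0.1t+\varphi_1)
 + a_{HF}\sin(2\pi\,0.25t+\varphi_2)\right) + \varepsilon(t)$$

crosses an integer threshold. IPFM was chosen over Gaussian jitter
because it makes frequency-domain targets *constructible*: a 0.1 Hz
modulation lands in the LF analysis band (0.04–0.15 Hz) and a 0.25 Hz
modulation in HF (0.15–0.40 Hz), so spectral-recovery tests have exact
expectations. Phases are drawn from the seed; the rate noise
$\varepsilon$ is white with sd `rri_noise` × (hr/60) per grid sample
(default 0.05, a mild broadband floor). Integration is trapezoidal on a
256-Hz grid with linear interpolation of crossing times, so a constant
60-BPM profile yields exactly sixty 1024-unit intervals per minute.
Intervals are expressed in the chest-strap sensor's device units of
1/1024 s and rounded to integers; quantization is therefore ±0.5 ms per
interval, which bounds time-domain feature agreement at about 1% for
sub-second intervals (the tests assert this bound explicitly).

### EEG: band-limited components

`generate_eeg()` sums, per channel, five independent Gaussian noise
components band-limited by FFT masking — one per rhythm (δ 1–4, θ 4–8,
α 8–12, β 12–30, γ 30–100 Hz) scaled to the profile's RMS amplitude in
µV — plus broadband white noise. FFT masking makes the generator's
confinement essentially exact: judged by a full-length periodogram
(0.05 Hz resolution at 20 s), out-of-band power is far below the 10%
leakage budget. Default amplitudes (δ 20, θ 10, α 10, β 5, γ 2 µV RMS,
noise 2 µV) follow typical scalp EEG magnitudes. The default sampling
rate is 500 Hz, the headband's advertised rate; the generator accepts
any rate above twice the highest band edge.

### The trainee plant

`plant_step()` relaxes heart rate (and theta, and a latent arousal)
toward a difficulty-dependent setpoint:

$$\mathrm{hr} \leftarrow \mathrm{hr} +
  \frac{\Delta t}{\tau}\,(s(d) - \mathrm{hr}) + \eta,$$

with τ = 20 s (the physiologic order of magnitude of an HR response to
a stressor) and HR noise sd 1 BPM·s^‑1/2, which gives a stationary HR
jitter of a few BPM — realistic short-term variability. The setpoint
map is linear in the normalized difficulty index: rest 70 BPM at index
0 up to 125 BPM at index 1, chosen so the 100–115 zone is reachable but
requires the controller to climb most of the difficulty range. Theta
runs the opposite way, 2.0 Bels at rest down to 1.5 Bels at maximal
load, mirroring the observed decline of frontal theta with difficulty.

The difficulty index is the mean of the six min–max-normalized
simulation variables (speed, target count, inverse size, hardness,
rain, darkness = 1 − daylight/10). No aggregation rule is prescribed by
the source material; the unweighted mean is the neutral choice and
makes the index monotone in every component-wise hardening.

### The cohort

`generate_cohort()` layers between-subject variability — Gaussian HR
offsets (sd 5 BPM) and multiplicative theta-amplitude jitter (sd 10%) —
over per-condition profiles. The default profiles encode the
characteristic trend: mean HR 75 / 88 / 96 / 105 BPM and frontal theta
amplitude 12 / 10 / 8.5 / 7 µV across baseline / easy / medium / hard.
The absolute levels are package choices (the source trends are
qualitative); they were fixed once, before any acceptance run, at
values a physiologist would call plausible for a mildly stressful
standing task. Blocks default to 180 s, matching the 3-min session
protocol.

What the generator does *not* emulate: respiration as an explicit
process (HF modulation is a fixed sinusoid), ectopic beats, EEG
artifacts (blinks, EMG), non-stationarity within a block, and any
coupling between EEG and ECG beyond their shared difficulty dependence.
A green parameter-recovery test therefore establishes that the
pipelines recover *constructed* effects at realistic noise levels — not
that they would behave identically on field recordings.

## Feature pipelines

### HRV

Intervals arrive in device units (1/1024 s) and convert by division.
SDNN uses the sample (n − 1) denominator; RMSSD is the root mean square
of successive differences; mean HR is 60 over the mean interval.
Spectrally, the tachogram (interval value at its beat time) is
resampled at 4 Hz by cubic spline — standard HRV practice; the
reference toolbox chain does not state its resampling, so this is a
documented choice — mean-detrended, and passed through a Welch
estimator with 256-sample Hann windows at 50% overlap (64-s segments at
4 Hz). Band powers are trapezoidal areas under the density with the
density linearly interpolated at the exact band edges, so disjoint
sub-bands tile exactly. VLF is reported even for 3-min blocks for
fidelity with the session protocol, although a 180-s window resolves
the 0.0033–0.04 Hz band poorly; treat short-block VLF as indicative.
No ectopic-beat filtering is applied; implausible intervals (outside
0.3–2.0 s) warn but are kept.

### EEG

The PSD uses 256-sample Hamming windows. The stated 90% overlap of a
256-sample window is 230.4 samples, which is not an integer; the hop is
fixed at 26 samples (overlap 230) because rounding here is a
reproducibility hazard worth pinning down. Absolute bandpower is
log₁₀ of the sum of PSD bins whose center falls in the half-open band
[lo, hi) — half-open so shared edges (4, 8, 12, 30 Hz) are never
double-counted. Log base 10 (Bels) matches the dB-style threshold
language used around these devices. One-sided density scaling is used;
the proprietary tool's scaling is unknown, and since every comparison
in the package is within-pipeline, only relative levels matter.

At 500 Hz a 256-sample window resolves ~2 Hz, so the narrow bands
(θ, α) span only about two bins and power injected at a band edge
spreads partly into the neighbor (up to a few tenths of a Bel for a
large edge-adjacent injection). The localization tests therefore use
mid-band spectral lines, which the estimator resolves cleanly
(cross-band movement < 0.001 Bels); users comparing narrow-band powers
across conditions should remember that band-edge energy is shared.

Indexes: engagement β/(α+θ) and the θ/β ratio are computed on
*linear* frontal-averaged band sums — ratios of log powers would be
scale artifacts — while frontal alpha asymmetry is α(Fp2) − α(Fp1) on
log powers, the asymmetry-literature convention. Both choices are
switchable (`use_log_ratios`). Frontal averaging is the arithmetic mean
of Fp1 and Fp2. TP9/TP10 are parsed and carried but excluded from the
indexes, which are frontal by definition here. Zero denominators yield
`NA` with a warning, not an error.

## The statistical battery

The design is repeated measures over four conditions, so the omnibus is
the Friedman test: within-participant mid-ranks,
χ² = 12/(nk(k+1))·ΣR²_j − 3n(k+1), df = k − 1 (= 3 for four
conditions). No tie correction is applied (plain form of the
statistic); on tie-free data the implementation matches
`stats::friedman.test` exactly, and on a small instance it matches an
exhaustive 1296-permutation oracle. The omnibus accepts k = 3 as well,
so shooting performance (undefined at baseline) can still be screened
with df = 2.

Post-hocs are Wilcoxon signed-rank tests in the specific variant that
reproduces the canonical all-same-sign result at n = 10: zero
differences dropped, T = min(W⁺, W⁻), and the normal approximation
*without* continuity correction,

$$Z = \frac{T - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24}},$$

which gives Z = −2.80, p = 0.005 when all 10 differences share a sign.
At n = 6 the approximation sits within ~0.05 of the exact
2⁶-enumeration p-value for tie-free ranks (asserted in tests). The
planned family is the four contrasts baseline-vs-easy/medium/hard and
easy-vs-hard, so the Bonferroni-adjusted level is 0.05/4 = 0.0125.

The normality screen is a Lilliefors-type KS test (distance from a
normal with estimated mean/sd). Rather than relying on published
approximation polynomials, the p-value comes from a Monte-Carlo null
table (2000 replicates, internally seeded by the sample size and
cached), making the screen self-contained and deterministic.

## SSQ scoring

The 16 items (0–3 each) load the three clusters through the published
binary matrix (seven items per cluster, each item loading one or two);
scale scores apply the weights 9.54 (nausea), 7.58 (oculomotor), 13.92
(disorientation) and 3.74 × the summed raw scores (total severity).
Flags use *strict* inequality against the cut-offs 9.5 / 15.2 / 0 / 15:
with a disorientation cut-off of 0, "any symptom at all" is the only
sensible reading, and it forces strictness for the whole set.

## The adaptation engine

The rule is a buffered zone controller. Metric samples stream into
30-sample sliding buffers (30 s at the 1-Hz plant sampling); every 5 s
the buffered means are compared against the target zone:

* HR below 100 BPM *and* theta above the concentration threshold →
  **increase** difficulty (speed +0.25 m/s, size ×0.9, targets +1,
  rain +0.1, daylight −0.5);
* HR inside 100–115 BPM → **hold**;
* HR above 115 BPM → **decrease** (the inverse step).

Only the increase branch is prescribed by the underlying
psychophysiological model; hold and decrease complete a bounded zone
controller. Buffer length and update period are package choices (the
source gives neither): 30 s of averaging suppresses the plant's
beat-scale jitter, and a 5-s period lets the controller traverse the
full difficulty range within one 3-min block.

Two design points deserve emphasis:

* **The step vector touches the environment variables.** With steps on
  speed, size and target count alone, the six-component difficulty
  index saturates at 0.5 and the HR setpoint (70 + 55·index) tops out
  at 97.5 BPM — the zone would be unreachable. The increase step
  therefore also raises rain and lowers daylight; hardness stays fixed
  (in the scenario design it is tied to the weapon's power).
* **The concentration gate defaults to 1.45 Bels.** The plant's theta
  setpoint spans 2.0 down to 1.5 Bels, so any threshold inside that
  range would close the gate at exactly the difficulties where the
  controller still needs its increase branch. The default threshold
  sits just below the hard-load floor: for the default plant the gate
  only trips on anomalous theta loss (e.g. a flat-lined sensor), which
  is its intended role. Raise it deliberately if you want
  concentration-limited adaptation.

Biofeedback gauges: calmness is 1 at the zone center, falling linearly
to 0 at twice the zone half-width; focus ramps affinely from 0.5 Bels
below the theta threshold (0) to the threshold itself (1). Both are
clamped to [0, 1].

Every emitted difficulty configuration is clamped to the hard variable
ranges (targets 3–20, size 0.3–3, speed 0–5 m/s, hardness 1–20,
daylight 0–10, rain 0–1); a fuzz test drives random decision sequences
and asserts the invariant throughout.

With all defaults, a 600-s session starting from the easy preset
settles its final-minute mean HR inside the target zone in 10/10 seeds
(asserted at ≥ 9/10 in the acceptance tests, allowing for stochastic
borderline seeds).

## Numerical and degenerate-input choices

* Welch segments are mean-detrended per segment; DC and Nyquist bins
  are not doubled in the one-sided density.
* Band integration interpolates the density at exact band edges
  (HRV bands); EEG bandpowers sum half-open bins, a deliberate
  asymmetry: AUC mirrors HRV toolbox practice, bin-summing mirrors the
  bandpower definition used around these headsets.
* Empty RR series, all-zero Wilcoxon differences, sub-minimum sample
  sizes, out-of-range difficulty values and non-uniform EEG sampling
  are errors; zero-variance normality samples and zero shots are
  flagged/NA rather than errors.
* All generators and the closed loop are pure functions of their
  arguments and a seed (`withr::with_seed` scoping); outputs embed the
  seed, package version and a config hash in comment headers.

## Runtime scaling in the tests

The null-cohort calibration (200 seeds) runs with 60-s RRI-only blocks
— the cohort spec's lower bound — purely for runtime; the
effect-recovery arm runs the full 180-s protocol with EEG at one seed.
The full-study test uses 5 trainees, 150-s blocks and 250 Hz EEG for
the same reason; the report contract it asserts is unchanged.

## Known limitations

* The plant is first-order and memoryless: no habituation, fatigue,
  anticipation, or performance feedback into physiology.
* VLF on 3-min blocks is retained for protocol fidelity but is not a
  resolved estimate.
* The Wilcoxon normal approximation is used at n = 10 because that is
  the variant the reported statistics imply; exact p-values would
  differ in the far tails.
* The EEG estimator's 2-Hz resolution shares band-edge energy between
  adjacent narrow bands (see above).
* The SSQ cut-offs are applied as given; their derivation (75th
  percentile of a calibration sample) is out of scope.
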