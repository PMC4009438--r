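---
title: "Hybrid NIRS-EEG command decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid NIRS-EEG command decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridbci)
```

This vignette is the package's account of the science it implements: the
block-design paradigm, the optical and electrophysiological signal models,
the decoding chain, and the places where the design was genuinely open and a
choice had to be made.

## The problem

A hybrid brain-computer interface splits four active tasks across two
modalities so that each is read from the brain region where it is most
discriminable: left- and right-hand tapping from motor-cortex EEG (C3/C4 in
the 10-20 system), and mental arithmetic versus mental counting from
prefrontal fNIRS (12 channels formed from 3 sources and 8 detectors at 760
and 830 nm). Each modality yields a two-class decision; the joint rest state
is the fifth command, Stop. Because only one region may be active at a time
under the paradigm, exactly one command is emitted per decision instant.

## The paradigm

`build_session()` lays out each 60-s data sample as

    rest(5) tap(10) rest(5) mental(10) rest(5) tap*(10) rest(5) mental*(10)

with the starred blocks using the opposite hand / opposite mental task. Five
samples make the canonical 5-minute session. This leaves a 20-s gap between
the end of one trial and the next onset of the same modality — long enough
for the hemodynamic response to settle. Which hand and which mental task come
first is not determined by the source material; the package defaults to
left hand and counting first, exposed as `first_hand` / `first_mental` so the
choice is explicit and reproducible.

EEG epochs run from +1 to +11 s after each tapping onset (10 s). NIRS
analysis windows are shifted by the hemodynamic onset lag instead
(`nirs_lag`, default 2 s — oxygenated hemoglobin typically starts rising
about 2 s after the prompt). Time is float seconds from session start;
blocks are half-open intervals `[onset, onset + duration)`.

## What the simulator emulates — and what it does not

Real recordings of this paradigm are not publicly deposited, so every
downstream stage is exercised against a synthetic generator with exported
ground truth. The generator emulates:

* **EEG**: 1/f (pink) background noise on all 8 channels (`eeg_noise`, RMS
  µV); at each 1-Hz tap a Gaussian-windowed burst at 21 Hz (inside the
  12–30 Hz beta band) on the channel contralateral to the hand, with
  `tap_amp_left > tap_amp_right` because the paradigm instructs stronger
  left-hand taps precisely so that amplitude carries the hand information.
  Per-tap amplitudes jitter log-normally (`tap_amp_jitter`).
* **Hemodynamics**: per mental block, a delayed smooth response — a gamma
  kernel starting `onset_lag` (2 s) after the prompt with ~9 s of support, so
  the 10-s block response peaks around task end and has decayed below 5 % of
  peak within `settle_time` (12 s) of task end. The two mental tasks differ
  in spatial weights across the 12 channels and in their HbR:HbO ratio
  (`w_arithmetic`/`w_counting`, `hbr_scale_*`), which is what makes them
  separable from channel-mean features. Block-to-block response gain varies
  log-normally (`response_gain_sd`, 0.3).
* **Optics**: the true concentrations are pushed through the forward modified
  Beer-Lambert model and contaminated in the optical-density domain with
  cardiac (1.1 Hz), respiratory (0.3 Hz) and Mayer-wave (0.1 Hz) sinusoids,
  white measurement noise, and — importantly — slow drifts (three sinusoids
  per channel drawn from 0.005–0.04 Hz). The drifts survive the low-pass
  filter by construction and are what limits rest-vs-task separability, as
  slow physiological oscillations do in real data.

The amplitudes and noise levels are generator tuning, not measurements: the
emulated study reports no SNR figures. They were chosen once so that the
synthetic pipeline behaves like a good-but-imperfect real session (binary
accuracies in the high-80s/90s rather than at ceiling). What passing tests
show is therefore that the *pipeline* is correct and robust at a realistic
operating point — not that any real cohort would achieve a particular
accuracy. The generator deliberately omits motion artifacts, eye blinks,
superficial-layer contamination and any realistic forward head model.

## The modified Beer-Lambert inversion

With optical density `A(t;λ) = ln(I_in(λ)/I_out(t;λ))`, concentration
changes follow from the two-wavelength system

    ΔA(t;λᵢ)/(l·d(λᵢ)) = α_HbO(λᵢ)·ΔcHbO(t) + α_HbR(λᵢ)·ΔcHbR(t)

solved per channel and time point (`mbll_invert()`). Three numerical
choices matter:

* **Baseline referencing.** `optical_density()` references the geometric
  mean intensity over the initial 5-s rest block (i.e. the arithmetic mean in
  the log domain, where the signal is linear). This cancels the incident
  intensity, baseline absorbance and scattering loss *exactly*, which is why
  the forward–inverse round trip recovers random concentration traces to
  better than 1e-9 µM in the tests rather than to within a Jensen-gap error.
* **Per-wavelength path lengths.** The printed form of the inversion has a
  single scalar `1/(l·d(λ))`, which is ambiguous when the differential
  path-length factors differ between wavelengths. The package divides each
  wavelength's ΔA by its own `l·d(λᵢ)` *before* the 2×2 inversion.
* **Constants.** Extinction coefficients default to standard published
  HbO/HbR molar extinction values at 760/830 nm (`hb_extinction`,
  µM⁻¹cm⁻¹); `l = 3` cm and `d = 6.0` at both wavelengths are typical
  adult-forehead values. All are overridable through `optics_config()`, and
  simulator and inverter share one such object in every test.

Denoising runs Gaussian low-pass first (unit DC gain, −3 dB at `cutoff`,
default 0.1 Hz: passes the ~0.017 Hz block-design fundamental, attenuates
respiration and cardiac pulsation), then wavelet thresholding (db5, level 4,
soft universal threshold `σ̂·√(2 ln N)` with `σ̂` from the finest-detail MAD).
The source material names both filters without ordering them; low-pass-first
is this package's choice, so the wavelet threshold is estimated on broadband
measurement noise rather than on cardiac oscillations. The discrete wavelet
transform is implemented in-package as a periodized orthogonal pyramid
(reflect-padding to a multiple of `2^level`), with perfect reconstruction
property-tested.

## EEG features

The beta band (12–30 Hz) is extracted with a causal order-4 Butterworth
band-pass — causal because the decoding chain claims online capability, so
zero-phase filtering is reserved for offline use behind a flag. Tap events
are peaks of the rectified, Gaussian-smoothed envelope (×π/2 so a sinusoid
of amplitude A reads ≈ A) that exceed the rest-baseline mean + k·SD
(default k = 2) with a refractory distance of half a tap period. The
feature pair is the mean detected peak amplitude on C3 and on C4; a channel
with no peaks contributes 0. Whether "mean peak amplitude" means signed
peaks or envelope magnitudes is ambiguous in the source; the package uses
envelope magnitudes.

One measurement-design detail: when counting the taps of a single block, the
detection window is the block shifted half a tap period earlier
(`detect_block_taps()`). The first tap falls exactly on the block onset, and
a window starting there would place that tap on the window edge where no
interior local maximum exists; the half-period shift centres every tap in
its own refractory cell.

## Classification

`fit_lda()` is a from-scratch two-class Fisher discriminant:
`w = Σ_pooled⁻¹(μ₁ − μ₀)` with the pooled (n−2 denominator) within-class
covariance, and bias at the midpoint of the projected class means shifted by
the log prior ratio. If the covariance is singular, a ridge of
`1e-6·trace(Σ)/p` is added. Exact boundary ties go to the first class
level, which is forced to be the rest/Stop class when present — on
ambiguity the interface emits no movement. The tests require the fitted
`(w, b)` to match `MASS::lda` to 1e-6 after scale normalisation on dozens of
random datasets, and require label-permuted cross-validation accuracy to sit
at chance; `MASS` is used only as an oracle, never in the implementation.

Evaluation uses stratified 5-fold cross-validation over decision windows,
seed-controlled. The four binary problems (Left/Right/Forward/Back vs Stop)
use trial-level features: the task analysis windows plus, per modality, rest
windows drawn from the rest blocks that follow *tapping* blocks. Rest blocks
that follow a mental block are excluded for NIRS because the hemodynamic
response is still washing out there — their inclusion would poison the
"Stop" class with residual activation. The evaluation protocol of the
original study (train/test split vs cross-validation) is not published, so
no attempt is made to reproduce its per-subject numbers from synthetic data;
the summary-statistics arithmetic on its printed table is reproduced exactly
instead (`aggregate_accuracies()`, sample SD, half-up display rounding).

## Fusion

`synchronize()` emits frames at the NIRS rate (1.81 Hz — the acquisition
documentation prints 1.81 and the analysis text 1.82; the package treats the
latter as a rounding inconsistency and fixes 1.81 as canonical). EEG
features are recomputed over a trailing 2-s window ending at each frame;
NIRS features are the latest preprocessed sample plus a trailing 3-sample
HbO slope. No frame uses future data, and truncating the input streams at
time t provably leaves all frames ≤ t unchanged (property-tested).

A modality is *active* when its feature magnitude exceeds the rest baseline
mean + 2 SD. NIRS additionally requires a positive trailing slope: after a
mental block the HbO level needs ~11 s to settle, and without the slope gate
every wash-out frame would re-trigger a command. Active EEG frames are
subclassified left/right, active NIRS frames arithmetic/counting, by the two
trained discriminants, and the five-command truth table does the rest:
left hand → Left, right hand → Right, arithmetic → Back, counting →
Forward, common rest → Stop. Simultaneous activity in both modalities is
impossible under the paradigm; as a safety default such conflicts resolve to
Stop with a flag. (Some descriptions of the paradigm suggest the crossed
mapping, left hand → Right; `decode_command(hand_mapping = "crossed")`
provides it, with the truth table as default.)

Per-frame ground truth for scoring accounts for the physics of the chain
rather than the raw block edges: EEG command windows are
`[onset, onset + 11 + 0.2]` (the trailing feature window plus the causal
filter's group delay), and NIRS windows are `[onset, onset + 14]`
(onset lag 2 s and ±2 s of symmetric low-pass smear). With all noise sources
disabled the decoder then reproduces every block's intended command and
emits Stop on every rest frame — the Stop-completeness property.

## Problem sizes and determinism

All simulations are deterministic given a seed; session batches derive
per-session seeds from one master seed. The test suite works at the scale a
desk check warrants: the canonical 5-sample (300 s) session for structural
checks, 2-sample sessions for repeated decoding runs, 100-trial Monte-Carlo
loops for the separability and round-trip properties, and a 20-session batch
for the headline ≥ 80 % decoding check. These sizes are the package's
choice of a thorough-but-quick verification level, and all thresholds were
fixed before the corresponding checks were run at scale.

## Known limitations

* The synthetic operating point is tuned, not measured; absolute accuracies
  on real recordings will differ.
* The fusion baseline is estimated from the training session; drifting
  baselines across sessions would need re-estimation or adaptive tracking.
* The decoder is conservative by construction (Stop on ambiguity, Stop
  during the hemodynamic rise), which depresses frame-level accuracy
  relative to block-level accuracy.
* Short-separation regression, motion-artifact correction and the fast
  optical response are out of scope, as are additional chromophores
  (cytochrome oxidase, water).
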