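---
title: "Methods: auditory EEG biomarkers and their synthetic validation"
author: "mouseEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory EEG biomarkers and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouseEEG)
```

## Scope

`mouseEEG` implements the standard battery of wireless mouse EEG biomarkers
used to characterize NMDA-receptor hypofunction models: paired-click
event-related potentials (N1 amplitude and S2/S1 sensory gating), basal and
evoked gamma/theta oscillation power, the 40 Hz auditory steady-state
response (power and intertrial coherence), mismatch negativity from a
flip-flop oddball design, and a mixed-model statistical layer with
Bonferroni-corrected contrast families.  Because animal recordings of this
kind are rarely deposited, the package pairs every analysis stage with a
synthetic-EEG generator that has explicit knobs for each biomarker, so the
whole pipeline is validated by parameter recovery rather than by reference
to a fixed dataset.

## Stimulation protocols

Three deterministic event-table generators produce the session timelines:

* **Paired clicks** (`make_paired_click_protocol`): 300 pairs by default,
  0.5 s within a pair, 10 s between pairs.  The long inter-pair gaps double
  as the reference segments for basal oscillation power.
* **ASSR trains** (`make_assr_protocol`): 100 trains of 2 s at 40 Hz with a
  30 s inter-train interval.
* **Oddball** (`make_oddball_protocol`): cycles of `deviant_period` tones,
  the deviant last, so the deviant fraction is exactly `1/deviant_period`
  (5% at the default every-20th placement).  Under the flip-flop design the
  two tone frequencies swap standard/deviant roles exactly at half the
  cycles.  We parameterize by cycles rather than by separate standard and
  deviant counts so the bookkeeping is internally consistent (a 600-cycle
  session contains 11,400 standards and 600 deviants).

Protocol timing carries no randomness: identical parameters give
bit-identical onsets.  Onsets are 0-based sample indices; stimulus windows
are half-open `[onset, onset + duration)`.

## The synthetic generator

`render_session` adds stimulus-locked structure to a noise floor:

* **Background**: 1/f ("pink") broadband noise (default sd 15 µV), plus
  stationary band-limited basal gamma (35-80 Hz, sd 8 µV) and theta
  (4-12 Hz, sd 10 µV) processes.  The basal band variances are the targets
  of the `basal_gamma_scale`/`theta_scale` drug knobs.
* **ERP family**: Gaussian-windowed deflections P1/N1/P80/P120 at
  20/40/80/120 ms with amplitudes +60/-120/+40/+25 µV (envelope sd
  5/8/15/20 ms), with per-trial latency jitter (about 2 ms) and 10%
  amplitude jitter.  Only latencies, amplitudes and widths matter to the
  implemented measures, so no attempt is made to reproduce measured
  waveshapes.  The absolute scale is a convention chosen so a healthy
  animal clears the 100 µV P1N1 inclusion floor with a comfortable margin;
  no quantitative waveform amplitudes are published for this preparation
  beyond that floor.
* **Gating**: the click-2 N1 amplitude is multiplied by `gating_factor`
  (default 0.5), making the generative S2/S1 ratio directly recoverable.
* **Evoked gamma**: a brief 50 Hz burst (sd 10 ms) time-locked near the P1
  latency, so the P1-anchored analysis window captures it.
* **ASSR**: a 40 Hz sinusoid for the train duration with per-trial phase
  offset drawn from `N(0, phase_jitter_rad_sd^2)`.
* **MMN**: the deviant N1 is multiplied by `deviant_n1_scale` (default
  1.5).  A drug's `mmn_scale` shrinks the *enhancement* toward 1
  (`1 + (deviant_n1_scale - 1) * mmn_scale`), so the identity effect
  reproduces the baseline bit-exactly.
* **Cohort structure**: each animal carries one persistent lognormal
  amplitude offset (sd 0.2, i.e. about 20% between-animal spread) applied
  across all its treatments - the generative counterpart of the random
  intercept in the statistical model.
* **Trigger**: a 10 ms, +500 µV rectangular pulse per stimulus on a
  dedicated channel; extraction uses a +250 µV rising-edge threshold, which
  recovers simulator-written events exactly.  ASSR trains carry one pulse
  at train onset.

The noise stream and the trial-jitter stream are seeded separately, so a
noiseless render plus a signal-free render reconstruct the full render
sample-for-sample; this additivity is asserted in the test suite.

What the generator does *not* emulate: biophysical cortical dynamics,
electrode geometry, movement artifacts beyond amplitude outliers, circadian
or habituation drift, and any coupling between biomarkers beyond the shared
amplitude offset.  Passing tests therefore demonstrate that the analysis
stages measure what they claim on signals with known structure - not that
real recordings satisfy the generator's assumptions.

## ERP analysis

Epochs span 200 ms pre- to 1000 ms post-stimulus (the 1200 ms bin at
1000 Hz).  Each trial/channel is baseline-corrected by subtracting its
pre-stimulus mean.  Trials whose peak-to-peak range exceeds 800 µV on any
channel are rejected; the criterion is a package choice (conservative for a
signal whose inclusion floor is a 100 µV P1N1), since no published
threshold exists for this preparation.  Components are measured on the
trial average: N1 is the most negative point in 30-50 ms, P1 the most
positive in 15-30 ms (a package default; only the component name "P20" is
standard, not a search window).  Ties break to the earliest sample.  The
gating ratio is `|N1(click2)| / |N1(click1)|` - the S2/S1 orientation, so
a gating deficit *increases* the readout, matching the direction language
used when such deficits are reported.

## Oscillation analysis

The time-frequency transform is a complex Morlet wavelet with `c = 5`
cycles (temporal sd `c/(2*pi*f)`), truncated at 4 temporal sds and
normalized to unit energy.  Layers sit at integer frequencies, 35-80 Hz
for gamma and 4-12 Hz for theta; a "logarithmic subdivision" of layers is
treated as a display convention, not an analysis choice, because integer
layers make the set reproducible.  Two numerical consequences are worth
knowing:

* Coefficients whose wavelet support crosses an epoch edge are flagged
  invalid and excluded from window means rather than zero-padded.  Theta at
  4 Hz needs ~0.8 s of context, so oscillation epochs are cut wider
  (-1.0 to +1.2 s) than ERP epochs.
* Under unit-energy normalization the amplitude response to a pure
  sinusoid peaks about `f/(2 c^2)` *below* the sinusoid's frequency
  (~1 Hz at 50 Hz with `c = 5`).  Band summaries are unaffected; single
  "peak layer" readouts are biased by one layer and tests allow for it.

Basal power is the mean band power in a 400 ms bin placed 3 s before each
click; evoked power is the total band power in a P1-anchored window (gamma:
±25 ms; theta: -20/+180 ms) minus basal power, and may be negative.
Anchoring to each animal's measured P1 absorbs individual latency
variation.  The subtraction is done in the power domain (all quantities
µV²; phase is not considered).

Normalization to the whole-recording band mean is computed spectrally: one
periodogram per channel weighted by the analytic Morlet frequency response
`|psi_hat(nu)|^2 = 2 sqrt(pi) sigma_t exp(-4 pi^2 sigma_t^2 (nu-f)^2)`.
This equals the time-domain mean of `|coef|^2` up to truncation and
boundary terms; on stationary noise the two agree to well under 1%.  Both
raw (µV²) and normalized values are reported, but the statistical layer
defaults to raw values.  The reason is structural: in the generator (and
plausibly in any recording dominated by background activity) the
whole-recording gamma mean is itself mostly basal gamma, so *normalized
basal* gamma is close to 1 by construction and cannot express a change in
basal power.  Normalization order (after basal subtraction) is a
configuration choice, as the published description does not fix it.

## ASSR analysis

Recordings are band-passed with a second-order Butterworth IIR filter,
cutoffs 5 Hz either side of the stimulation frequency (35-45 Hz at 40 Hz),
applied forward-backward for zero net phase shift.  Epochs are 2.8 s
(400 ms pre-trial, 2 s trial, 400 ms post-trial).  Power is the
accumulated (summed over trial-window samples) 40 Hz Morlet-layer power,
averaged across trials - "accumulated" is read as a sum; the choice affects
scale, not contrasts.  Intertrial coherence normalizes each trial's complex
coefficient to unit magnitude, averages across trials per time point, and
takes the modulus:

* identical trials give ITC = 1 exactly;
* Gaussian phase jitter of sd sigma gives `E[ITC] ~ exp(-sigma^2/2)`;
* uniform random phase gives the Rayleigh resultant `~ sqrt(pi/(4 n))`.

The scalar per condition is the time-mean of the ITC curve over the trial
window (a median is available; the published analyses report one number
per condition without stating the reduction).  ITC is invariant to common
phase rotations and per-trial amplitude scaling, and power and ITC are
functionally independent axes (amplitude moves power, jitter moves ITC);
all three properties are asserted by simulation.

## MMN analysis

Each deviant is paired with the last standard preceding it in its block,
guaranteeing equal trial counts in both averages.  Epochs are 100 ms pre-
to 400 ms post-tone (inside the 550 ms inter-onset interval); artifact
rejection is applied pairwise so counts stay equal.  The difference wave is
deviant minus standard; the MMN peak is its most negative point in a
20-100 ms search window (configurable - the published peak detection names
a software function, not a window), and the MMN magnitude is the
trapezoidal integral over peak ±25 ms, in µV·ms, negative for a genuine
MMN.  The robustness screen takes `|N1(standard)| / |N1(deviant)| >= 0.5`;
the published ratio is never given a formula, and this reading - which the
enhanced-deviant generator satisfies at about 0.67 - is a documented
choice.  Channel-mean waveforms are used where two auditory-cortex
channels exist.

## Statistical layer

Each parameter is modeled as `value ~ treatment + (1 | animal)`, and the
predefined contrasts are each dose versus vehicle-at-baseline plus washout
versus baseline.  P-values and degrees of freedom use the Satterthwaite
approximation (`lmerTest`); the original analyses were run in another
environment without stating a df method, so calibration is established by
simulation instead: over 1000 null cohorts of 12 animals the type-I error
at the adjusted level stays within 3 binomial sds of nominal.  When the
between-animal variance is estimated as zero, the model is singular and
the function falls back (with a warning) to the equivalent fixed-effects
analysis with animal as a blocking factor.  Two-sided 95% confidence
intervals accompany every estimate.

The Bonferroni family is the set of dose-by-parameter tests within one
protocol: `alpha* = 0.05 / (n_doses * n_parameters)` with 6 ERP, 2 ASSR
and 1 MMN parameters (e.g. 0.05/6 for one dose of the ERP family, 0.05/18
for three doses).  The washout-versus-baseline contrast is a
return-to-baseline check and is tested at 0.05 outside the family.
Cohorts with a parallel vehicle group can be pooled into the same model;
within-group contrasts are the default reporting.

## The demonstration cohort

`default_config()` encodes a desk-scale experiment: 12 animals, vehicle
baseline plus a high-dose antagonist-like effect (`n1_scale = 0.5`,
`basal_gamma_scale = 2`, `evoked_gamma_scale = 0.4`, `assr_amp_scale =
0.5`, `assr_jitter_add_rad = 1`, `mmn_scale = 0.3`), and session sizes
reduced from the full protocols - 40 click pairs at a 5 s inter-pair
interval, 30 ASSR trains at a 4 s inter-train interval, 30 oddball cycles
- so a full simulate-analyze-model run completes in about three minutes.
The reduced sizes keep every analysis constraint intact (the basal bin at
-3 s still fits inside the inter-pair gap; ASSR epochs keep their 400 ms
margins).  Under this configuration the six headline contrasts reproduce
the qualitative antagonist pattern - N1 down, basal gamma up, evoked gamma
down, ASSR power down, ITC down, MMN down - each significant at its family
level; the full-size sessions remain the defaults of the protocol
generators themselves.

## Numerical and I/O details

* Wavelet truncation at 4 temporal sds; coefficients are `sum x(tau)
  conj(psi(tau - t)) / fs` via FFT linear convolution, with a direct
  inner-product path for narrow output windows (the two paths agree to
  float precision, and both match an independent direct-convolution oracle
  to better than 1e-6 relative error).
* EDF files are plain EDF: 16-bit little-endian samples, µV physical unit,
  one-second records, symmetric per-channel physical ranges chosen from the
  data (quantization step `range/65535`), zero-padded final record.
  Mixed per-channel sampling rates are rejected; a truncated file is a
  format error, not a partial object.  EDF+ annotations are not used.
* Event labels are reconstructed from inter-onset intervals (tolerance ±5
  samples), because pulse channels carry no codes.
* Trapezoidal integration at native sampling for the MMN AUC; signed AUC
  retained.
* All tie-breaks go to the earliest sample.

## Known limitations

* The generator's drug effects are multiplicative and instantaneous; no
  pharmacokinetics, tolerance, or time-on-task drift.
* Evoked and basal contributions are additive and uncorrelated by
  construction; real cross-frequency or evoked/induced coupling is out of
  scope.
* P80/P120 (P3-like) components are rendered but not quantified, and the
  20 Hz ASSR variant exists behind an argument without an acceptance
  surface.
* Absolute simulated amplitudes are conventions; only ratios, differences
  and directions are meaningful across conditions.
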