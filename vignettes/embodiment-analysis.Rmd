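---
title: "Methods: gaze-based inference for artificial-limb embodiment in mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-based inference for artificial-limb embodiment in mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embodir)
```

## The experimental paradigm and what the package computes

`embodir` analyses rubber-hand-illusion experiments translated to the
head-fixed mouse. In each trial the mouse first sits idle for 120 s (the
baseline), then for 120 s its hidden real forelimb and a visible artifact
(a limb-shaped replica, or a featureless block as a shape control) are
stroked by motorized brushes — either synchronously or at independent random
times (the asynchronous negative control). At 240 s a sharp object is
rapidly moved next to the artifact and held there for 10 s. The behavioral
readout is videographic: the face is filmed at 200 Hz from both sides and a
markerless pose estimator tracks the pupil centers, two vertical
pupil-margin points per eye (their separation is the pupil diameter), the
left ear and one left whisker.

The scientific question is whether, after synchronous pairing, the mouse
treats the artifact as its own limb — operationalized as a longer-lasting
gaze shift toward the threatened artifact in the synchronous than in the
asynchronous condition. The package turns this into a reproducible
statistical pipeline:

1. **Condition-difference trace.** For each mouse, session traces are
   averaged within condition (trials are never pooled across mice), and the
   pointwise synchronous − asynchronous difference of the toward-threat
   signal is formed over the analysis window from 1 s before to 10 s after
   threat onset (11 s). The across-mice mean ± SEM of these per-mouse
   differences is the group difference trace.
2. **Max-statistic bootstrap threshold.** Any sample-wise test over a 2,200
   sample window needs family-wise error control. The null material is the
   120 s pre-pairing baseline: per mouse, the difference between the
   baseline of the synchronous-trial recording and that of the
   asynchronous-trial recording. Each bootstrap iteration draws one
   uniformly random, frame-aligned 11 s segment per mouse (independently
   per mouse and iteration), averages the segments across mice, and keeps
   the maximum of the averaged series. The 95th percentile of 10,000 such
   maxima is the 5% family-wise threshold: under the null, the chance that
   the observed trace exceeds it *anywhere* in the window is 5%.
3. **Window detection and quantification.** Runs of supra-threshold samples
   are merged across gaps ≤ 50 ms, runs shorter than 100 ms are discarded,
   and the first two surviving runs are labeled W1 (the fast threat-onset
   excursion) and W2 (the sustained gaze). Per mouse and condition, the
   mean of the pre-threat-normalized trace over each window is computed,
   and the two conditions are compared with a two-sided Wilcoxon
   signed-rank test, exact for n ≤ 25.
4. **Difference of differences.** To compare the limb and block
   experiments, the same machinery is applied to the per-mouse second-order
   series (limb sync−async) − (block sync−async), with the null built from
   the second-order baseline differences.

Two normalizations are used for display versus inference. Raw-trace
displays subtract the 120 s baseline mean (correcting slow per-trial
offsets); threat-response displays and window quantification subtract the
mean of the 1 s immediately before the threat. The significance analysis
itself runs on **unnormalized** differences: subtracting a baseline would
remove exactly the slow fluctuations the bootstrap must see to calibrate
the threshold.

## Design choices in the inference core

* **Signed versus absolute maximum.** The threshold is built from the
  maximum of the *signed* averaged segment, making the test one-sided
  toward the threat, which matches the directional hypothesis (gaze
  *toward* the artifact). An `mode = "absolute"` flag provides the
  two-sided variant; both are exposed because the choice is a genuine
  convention, and the calibration property holds for either as long as
  trace and null use the same mode.
* **Threshold convention.** The empirical quantile is the order statistic
  at `ceiling(quantile_level * n_boot)` (inverse-CDF convention) — exact,
  monotone in the level, and stable across platforms.
* **Segment starts** are uniform over all frame-aligned starts in
  `[0, baseline_length − segment_length]`, drawn with replacement across
  iterations and independently per mouse. A `start_stride` option restricts
  starts to a coarser grid (e.g. whole seconds), which is what makes the
  exhaustive-enumeration oracle in the test suite feasible.
* **Window extraction rules** (100 ms minimum duration, 50 ms merge gap,
  windows ordered by onset) are configuration, not facts about the
  paradigm; they are surfaced in every report. The defaults are an order of
  magnitude shorter than the phenomena of interest (the fast excursion
  lasts hundreds of ms, the sustained gaze seconds), so results are
  insensitive to them in the regimes the tests probe.
* **Sessions.** Baseline difference series are averaged per mouse across
  sessions before bootstrapping. Averaging and differencing commute, so
  this equals differencing the per-condition mean baselines, which is how
  it is computed.
* **Wilcoxon signed rank.** Zero differences are dropped, tied magnitudes
  midranked, and for n ≤ 25 the two-sided p comes from the exact
  distribution of the positive-rank sum over all 2^n sign assignments
  (computed by convolution over doubled midranks, which enumerates the same
  distribution without 2^n work; the two-sided tail is the probability of
  a rank sum at least as far from its mean as observed). Above n = 25 a
  tie-corrected normal approximation takes over. `stats::wilcox.test`
  cannot serve here because its exact path refuses ties and zeros; it is
  used in the test suite as an independent oracle on tie-free fixtures.

## The synthetic cohort generator

The generator exists so every stage is testable without the deposited
videography data. It simulates at the level of tracked coordinates — no
video — and emulates:

* the protocol timeline (120 s baseline, 120 s pairing, threat at 240 s
  held 10 s, 200 Hz) and stroke trains with inter-onset intervals drawn
  from an exponential law truncated to [0.6, 2.0] s (untruncated rate 1/s).
  A literal "Poisson-distributed intervals in [600, 2000] ms" is
  self-contradictory — Poisson interval laws are unbounded — so the
  truncated-exponential reading preserves memorylessness within the stated
  bounds; the law is recorded in the manifest. In the synchronous mode the
  tactile train duplicates the visual one; in the asynchronous mode the two
  are drawn independently.
* per-mouse baseline heterogeneity: a horizontal offset drawn once per
  mouse (sd 5 px), mirroring the diversity of resting pupil positions
  across animals;
* tracking noise: a stationary Ornstein–Uhlenbeck process (exact
  discretization, default sd 1 px, correlation time 0.5 s) plus white
  measurement noise (0.1 px). The autocorrelation is essential: with white
  noise the 11 s-segment maximum would be nearly constant and the bootstrap
  would be trivially calibrated;
* a biphasic threat response on the horizontal pupil axis, signed toward
  the threat with a per-camera-side sign stored in the manifest: a fast
  difference-of-exponentials excursion (latency 0.1 s, rise 0.05 s, decay
  0.5 s) and a sustained plateau on [1, 7] s post-threat with exponential
  decay afterwards. The plateau is exactly flat so that Monte-Carlo tests
  of window means have a closed-form target;
* condition-dependent amplitudes ordered
  limb-sync > limb-async ≥ block-sync ≥ block-async > threat-only
  (defaults 3, 1.5, 1.5, 1, 0.25 px sustained), the ordering the paradigm
  predicts: strongest sustained gaze after synchronous pairing with the
  limb-shaped artifact, and only a small reflex without pairing;
* pupil dilation carried by the vertical separation of the pupil-margin
  points, ear/whisker movement bursts after the threat, and tracker
  failures (1% of frames get a large excursion with confidence below 0.5),
  which exercise the gap-interpolation stage.

Randomness is organized in derived substreams (cohort → trial → tracked
point), so cohorts are bit-reproducible and generating a subset of points
yields identical series for the shared points. That is how the calibration
studies can simulate only the right pupil at full 200 Hz scale without
changing its statistics.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: saccade microstructure and oculomotor
dynamics, blinks with structured artifacts, stimulus-locked whisking during
pairing, slow non-stationary drift across a session, or any coupling
between the tracked points beyond the shared condition templates. The
calibration result says the inference chain is correct *given* stationary
autocorrelated noise; it cannot say the real data satisfy that assumption.

## Numerical choices and degenerate inputs

* Gap interpolation is linear between flanking valid samples, with
  edge gaps held at the nearest valid value and a hard error when no valid
  sample remains; the confidence threshold defaults to 0.9.
* All windows are half-open `[start, end)` in seconds; frame `i` covers
  time `(i-1)/rate`, which keeps the 11 s window at exactly
  `11 × frame_rate` samples and makes normalization windows disjoint from
  what follows them.
* Tracking CSVs are written with shortest-exact decimal formatting, so
  `read(write(x))` is the identity to the bit; missing samples become empty
  cells and are surfaced as `NaN` with confidence 0.
* Degenerate cases have defined behavior: all-zero baselines give a zero
  threshold; an empty supra-threshold set is a valid (empty) report;
  all-zero paired differences give p = 1 with a warning; a schedule with
  `min_interval == max_interval` degenerates to a deterministic train.
* The bootstrap inner loop runs in compiled code; segment starts are drawn
  on R's RNG so results are a pure function of the seed.

## Problem sizes used in the validation studies

The test suite and the reproduction script run the calibration study at
400 replicate null cohorts (10 mice each, one session, full 200 Hz
timeline) with 1,000 bootstrap iterations per cohort — enough for the
family-wise rate to be constrained to its 95% binomial interval of about
±2.1 percentage points — and the recovery study at 100 replicates per
condition with a 3 px (3 × noise sd) injected plateau. Unit tests use a
shortened timeline (5 s baseline, threat at 10 s, 25–50 Hz) where the same
code paths run in milliseconds; nothing in the implementation depends on
the timeline constants.

## Known limitations

* The bootstrap draws its 11 s null segments from 120 s of baseline per
  mouse — barely eleven non-overlapping segments, so the resampled maxima
  underestimate the variability of a genuinely independent window slightly.
  In the calibration study this shows up as a family-wise rate a point or
  two above the nominal 5% (within the binomial interval of a 400-cohort
  study); the effect is a property of the resampling design itself — it
  persists when the simulator is replaced by idealized stationary inputs —
  and shrinks as the baseline lengthens relative to the analysis window.

* The per-signal analyses are deliberately independent: no multiplicity
  correction is applied across signals (right/left pupil, diameter, ear,
  whisker), matching the paradigm's reporting conventions.
* The exact W1/W2 labeling takes the first two surviving runs by onset; a
  pathological trace with three genuine excursions would fold the third
  into the report's interval list but not into a labeled window.
* The normal-approximation branch of the signed-rank test (n > 25) is never
  exercised by cohorts of realistic size; it exists for completeness.
* `read_manifest` validates structure and labels but trusts file contents
  until they are read; a corrupted tracking file fails at `run_full_analysis`
  with the offending trial named.
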