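---
title: "Quantifying REM-sleep motor activity across EMG, actigraphy, and video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying REM-sleep motor activity across EMG, actigraphy, and video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remmotor)
```

## The measurement problem

In REM sleep behavior disorder (RBD) the atonia that normally suppresses
movement during REM sleep fails, and motor activity — from small twitches to
violent dream enactment — appears precisely in the stage where healthy
sleepers are stillest. Three instruments see this activity through different
physics: surface EMG of the forearm flexors measures muscle activation
whether or not the limb moves; infrared video shows displacement but misses
what bedding hides; wrist actigraphy measures acceleration, catching
movements EMG electrodes are not placed to see and video cannot resolve.
`remmotor` provides the machinery to put all three on a common time base
(3 s mini-epochs within REM periods) and quantify how much they agree, per
participant and across a cohort.

## The activity-count model

The actigraphy arm of the pipeline converts raw tri-axial wrist acceleration
into a 1 Hz non-negative "activity count" series:

1. **Autocalibration** (`calibrate()`). A single global gain is chosen so
   the median vector magnitude over still windows equals 1.000 g. A window
   is *still* when the SD of its magnitude over `window_s` (default 10 s)
   falls below `stillness_threshold` (default 0.013 g — comfortably above
   accelerometer noise, far below any overt movement). We deliberately fit
   one scalar gain rather than a per-axis offset/gain sphere: it matches the
   stated calibration goal exactly, is testable (a recording scaled by 0.9
   must recover gain 1/0.9), and cannot silently rotate axes.
2. **Resampling** (`resample_recording()`, default 25 Hz) harmonizes device
   rates before feature extraction. Downsampling applies a zero-phase
   low-pass Butterworth (cutoff at 90% of the target Nyquist) per axis,
   then linear interpolation onto the uniform target grid.
3. **ENMO** (`enmo()`): per-sample `sqrt(x² + y² + z²) − 1`, in g. On a
   calibrated still wrist this is zero-mean; movement shows as magnitude
   deviations.
4. **High-pass filtering** (`design_highpass()`, `apply_zero_phase()`):
   a minimal-order Butterworth high-pass meeting 80 dB stopband attenuation
   at 0.1 Hz with ≤1 dB passband ripple from 0.5 Hz, applied
   forward–backward so the output has zero phase shift.
5. **Rectification, 1 s binning, zero-rounding**: negative filtered values
   are clipped to zero, samples are averaged within whole seconds (partial
   tail seconds dropped, never padded), and any count below 0.1 is rounded
   down to zero.
6. **Epoch classification** (`epoch_activity()`): a 3 s mini-epoch is
   active iff the maximum of its 1 s counts exceeds zero — equivalently,
   iff any of its seconds reaches the 0.1 floor.

### Where the filter runs, and why

The composition order deserves explanation, because the naive reading — bin
to 1 Hz first, then high-pass with a 0.5 Hz passband edge — is internally
impossible: 0.5 Hz *is* the Nyquist frequency of a 1 Hz series. Worse, a
1 s average is itself approximately a 0.5 Hz low-pass, so following it with
any filter that passes only ~0.45 Hz and above annihilates exactly the brief
phasic bursts the model is meant to count (we measured a 0.5 g, 1 s burst
collapsing from a binned count of 0.16 to 0.02). The same cancellation
occurs if one filters the signed 25 Hz ENMO and then averages, because the
average extracts precisely the low-frequency content the filter removed.

The composition that is both spectrally coherent and faithful to the stated
design targets is therefore: filter the **signed** ENMO at the harmonized
25 Hz rate — where the 0.1 Hz/80 dB and 0.5 Hz/1 dB targets are directly
achievable (an order-7 Butterworth; −93 dB measured at 0.1 Hz) — then
**rectify**, then bin. Rectification is a nonlinearity that moves burst
energy back toward DC, which is what lets a 1 s average retain it. This is
the default (`filter_stage = "raw"`). The literal reading (clipped ENMO →
1 s bins → 1 Hz filter with the passband edge clamped to 0.45 × rate) is
implemented as `filter_stage = "binned"` for comparison; its attenuation of
phasic activity is demonstrated in the test suite.

### Zero-phase filtering details

`apply_zero_phase()` implements forward–backward filtering with
odd-reflection padding (three filter orders at each end) and steady-state
edge initialization: the signal is extended with a constant run long enough
for the slowest pole to decay below 1e−12, so a constant input maps to
numerically zero output with no edge transient (the stock
`signal::filtfilt` leaves O(0.01) edge artifacts on DC, which would leak
through the 0.1 zero-rounding floor on long recordings). Both FIR and
recursive passes run in C via `stats::filter`. The residual asymmetry of
time-reversal is confined to the padded edge region and is bounded in the
tests.

## Grid, EMG rule, and merging

REM periods are maximal runs of consecutive R-staged 30 s epochs; a single
intervening non-R epoch splits a period (the strictest reading — period
segmentation is not otherwise defined). Periods shorter than 5 min are
excluded, with *exactly* 5 min kept (the rule is strict "shorter than").
Each period is tiled from its onset with 3 s bins; with 30 s staging the
tiling is exact.

The EMG scorer thresholds a rectified envelope at twice the atonia baseline,
where the baseline is the minimum amplitude within the REM period or — if
lower — within the preceding non-REM segment. Two unstated points are
resolved as follows and exposed as parameters:

* *Look-back extent*: "preceding non-REM period" is taken as the full
  interval since the previous REM period (or the recording start).
* *Runs longer than 5 s*: the scored burst window is 0.1–5.0 s; longer
  suprathreshold runs (tonic activity) are **not scored but flagged** in a
  `sustained` attribute rather than silently dropped, so downstream users
  can audit them.

A zero atonia baseline makes the relative threshold undefined; the scorer
stops with an explicit error rather than guessing a floor. Because the
threshold is relative, scoring is invariant under uniform envelope
rescaling (a tested property).

Side merging is an element-wise OR (active if either wrist is active);
timelines are all seconds from a single recording-start origin with
half-open `[start, end)` intervals, and device clocks are aligned by
cross-correlating the vector-magnitude artifact of a brisk-arm-maneuver
(`estimate_sync_offset()`; a peak correlation below 0.5 yields a warning
and offset 0 rather than a spurious shift).

## Agreement statistics

All agreement quantities operate on binary label vectors over one grid.
Conventions that matter:

* 2×2 tables are oriented first-modality-by-rows; every reported
  conditional probability names its direction explicitly
  (`p_first1_given_second1` is P(A = 1 | B = 1) for
  `contingency_2x2(A, B)`). A zero conditioning margin yields `NA`, never a
  division by zero; κ with two constant raters is `NA` with a warning.
* Multi-epoch events count as independent active epochs in κ and
  conditional probabilities; run-merging into onset-to-offset events applies
  only to the activity *rate* (events per REM hour), where runs never span
  period boundaries.
* "Pooled" odds ratios across participants use the Mantel–Haenszel
  estimator with the Haldane–Anscombe 0.5 correction applied to any table
  containing a zero cell, and Robins–Breslow–Greenland standard errors on
  the log scale. (Epoch-pooling across participants is a different, also
  defensible reading; with per-participant tables available, MH is the
  standard choice and is cross-checked against `metafor::rma.mh` in the
  tests.)
* Group-level confidence intervals resample **participants** with
  replacement (B = 10,000, percentile method, seeded); with nine
  participants an interval bound moves by roughly ±0.01–0.02 across seeds,
  which is the resolution at which such intervals should be read.

Stage-wise movement load is the summed left+right 1 Hz counts per minute of
each stage. Pairwise stage comparisons use exact signed-rank distributions
for small samples, with zero differences dropped, under Holm correction
across the six pairs of {N1, N2, N3, R}; wake is computed but excluded from
testing. The six-pair family is the conservative choice where the tested
family is not enumerated; it is configurable.

## The synthetic-data generator

The generator exists so that every downstream stage has a ground truth. It
emulates: a first-order Markov hypnogram over {W, N1, N2, N3, R} with
realistic bout structure; stage-dependent homogeneous Poisson motor events
(defaults: 2/min in REM vs 0.1–0.5/min in NREM — the RBD premise — and
6/min in wake); log-normal event durations (median 1 s) and burst peak
amplitudes (median 1 g); left/right/bilateral involvement; accelerometry as
a unit gravity vector plus Gaussian noise plus, per event, a raised-cosine
envelope times a rectified 3 Hz oscillation along the gravity axis; an EMG
envelope as an atonia baseline plus 3×-atonia raised-cosine bursts for
events passing a per-event detection draw; and per-epoch annotation labels
with per-modality detection probabilities and false-positive rates.

Choices worth recording:

* **Burst direction.** Bursts ride along the gravity axis because ENMO
  responds *linearly* to magnitude deviations in that direction; an
  orthogonal burst enters ENMO only as `sqrt(1 + a²) − 1 ≈ a²/2` and
  sub-g events would be invisible. With the default waveform the binned
  count is ≈0.145 × peak amplitude, so the 0.1 floor corresponds to
  ≈0.7 g — the generator's amplitude median of 1 g then yields the
  clinically observed ordering (actigraphy and EMG comparable, video
  lowest).
* **Events never straddle stage bouts** (durations truncated at bout end),
  keeping stage attribution unambiguous. Bilateral events render with
  identical onsets on both sides.
* **Annotation route for actigraphy.** The physical route (render →
  counts → epoch rule) renders *every* event, so it cannot express a
  per-event detection probability; `render_modality_annotations()` accepts
  `"acti"` so that observation-model recovery (estimated
  P(Acti = 1 | EMG = 1) converging to the generative probability) can be
  tested with the same machinery as EMG and video.
* **One global seed expands into named sub-streams** (hypnogram, events,
  per-side noise, per-modality detections), so each stream is independently
  reproducible.

What the generator does **not** emulate: real movement kinematics (all
waveforms are smooth parametric stand-ins), physiological EMG waveforms
(envelope only), EEG, respiration, scorer disagreement, device-specific
transfer functions, or temporal misalignment beyond a constant offset.
Passing tests therefore demonstrate that the pipeline's logic and statistics
are correct under a known generative model — not that any particular
clinical sensitivity figure transfers to real recordings.

## Numerical choices and degenerate inputs

* Negative ENMO: clipped at the stage appropriate to the filter variant
  (after filtering in `"raw"`, before binning in `"binned"`); neither is
  stated by the activity-count model's published description, so both are
  explicit parameters.
* Partial tail bins and epochs are dropped, never padded.
* Zero-rounding uses strict "less than" (a count of exactly 0.1 survives).
* Missing stages in movement load are `NA`, never 0; unilateral input is
  flagged, not silently accepted.
* Degenerate agreement inputs (constant raters, zero margins, empty
  categories, all-degenerate OR tables, nights without usable REM) return
  flagged missing values or explicit errors — whichever makes silent
  misinterpretation impossible.
* ADC quantization (12-bit vs 16-bit devices) is off by default and
  available via `quantize_recording()`.

## Problem sizes used in validation

The shipped test suite and acceptance script run in minutes on one CPU. The
bundled reference-cohort tables (nine participants) drive the worked
examples exactly; synthetic checks use 30 min–5 h nights at 25 Hz: the
detection-probability recovery uses ≈600 events over 300 min of REM, and the
REM-dominance power property uses 9 simulated participants × 20 replicates
of 30 min block-structured nights with REM event rates 10× NREM. These sizes
were chosen as the smallest at which the binomial and signed-rank statistics
under test are comfortably resolved.

## Known limitations

* The activity-count model follows a published verbal description whose
  composition order is not fully specified; we chose the spectrally
  coherent reading and exposed the literal one. Absolute count values are
  therefore comparable *within* this implementation, not necessarily across
  implementations.
* Weighted or multi-rater κ, event-level (time-warped) matching across
  modalities, and diagnostic classification are out of scope.
* Video scoring is input-only: the package never derives labels from
  pixels.
* Proprietary device binaries are not parsed; accelerometry enters as CSV.
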