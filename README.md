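# remmotor

Multimodal quantification of motor activity during REM sleep, for REM sleep
behavior disorder (RBD) research.

RBD is a parasomnia in which the normal near-paralysis (atonia) of REM sleep
is lost, so dream enactment leaks out as twitches, jerks, and complex
movements. Three modalities are used to measure this motor activity —
forearm EMG, infrared video, and wrist actigraphy — and they capture
partially overlapping phenomena. `remmotor` implements, as a tested R
pipeline, the analysis needed to compare them within synchronized REM sleep:

* **Actigraphy activity counts.** Raw tri-axial wrist acceleration is
  autocalibrated so the vector magnitude is 1 g at rest, resampled to a
  harmonized 25 Hz, converted to per-sample ENMO
  (`sqrt(x² + y² + z²) − 1`), high-passed with a zero-phase
  (forward–backward) IIR Butterworth filter (80 dB stopband attenuation at
  0.1 Hz, ≤1 dB passband ripple from 0.5 Hz) to remove baseline drift,
  rectified, averaged into 1 s bins, and zero-rounded (counts < 0.1 → 0).
  A 3 s mini-epoch is *active* if its maximum 1 s count exceeds zero.
* **Mini-epoch grid.** 30 s hypnograms are segmented into REM periods
  (runs of consecutive R epochs; periods shorter than 5 min excluded), and
  each period is tiled with contiguous 3 s mini-epochs — the common unit for
  all cross-modality comparisons.
* **EMG scoring.** A rectified EMG envelope is scored per mini-epoch by
  rule: within each REM period the atonia baseline is the lowest envelope
  amplitude in that period (or the preceding non-REM segment, if lower);
  a burst is a suprathreshold run (≥2× atonia) lasting 0.1–5.0 s; an epoch
  is active if it overlaps a qualifying burst. Video labels are manual
  binary annotations read as input. Left/right labels merge by OR.
* **Concordance statistics.** Seven-region overlap decomposition
  (EMG/actigraphy/video alone, each pair, all three), Cohen's κ,
  directional conditional probabilities such as P(Acti = 1 | EMG = 1),
  Mantel–Haenszel pooled odds ratios with Haldane–Anscombe correction,
  activity ratio (% of REM mini-epochs active) and activity rate
  (onset-to-offset events per REM hour), consensus-stratified activity
  counts, and participant-level bootstrap confidence intervals.
* **Stage-wise movement load.** Summed left+right counts per minute per
  sleep stage, compared with exact Wilcoxon signed-rank tests under Holm
  correction; between-group contrasts use Mann–Whitney with Cliff's δ and
  Benjamini–Hochberg adjustment.
* **Synthetic data.** A generative model of a full multimodal night
  (Markov hypnogram, stage-dependent Poisson motor events, burst-shaped
  accelerometry over gravity plus noise, EMG envelope bursts over an atonia
  baseline, probabilistic per-modality annotations) so every stage of the
  pipeline is testable with known ground truth.

## Worked example

Simulate a four-hour multimodal night, run the pipeline, and compare
modalities on the REM grid:

```r
library(remmotor)

cfg <- sim_config(seed = 7)
sim <- simulate_participant(cfg, n_epochs = 480, seed = 7)

counts_L <- compute_activity_counts(sim$accel$L)
counts_R <- compute_activity_counts(sim$accel$R)
acti <- merge_bilateral(epoch_activity(counts_L, sim$grid),
                        epoch_activity(counts_R, sim$grid))
emg  <- merge_bilateral(score_emg_mini_epochs(sim$emg$L, sim$periods, sim$grid),
                        score_emg_mini_epochs(sim$emg$R, sim$periods, sim$grid))

overlap_regions(emg, acti, sim$video)
#> <overlap_counts> n=850, union=81 (EMG=57, Acti=46, Video=52)
#>   emg_only  acti_only video_only   emg_acti  emg_video acti_video  all_three
#>         11          6         11         12         13          7         21

t_ea <- pair_table(overlap_regions(emg, acti, sim$video), "emg", "acti")
round(cohens_kappa(t_ea), 2)
#> [1] 0.62
round(movement_load(counts_L, counts_R, sim$hypnogram), 2)
#>   N1   N2   N3    R    W
#> 0.10 0.06 0.02 0.34 1.08
```

The overlap counts say that of 850 REM mini-epochs, 81 contained activity
detected by at least one modality, 21 by all three; κ = 0.62 is the
chance-corrected epoch-level agreement between EMG and actigraphy. The
movement-load row shows the RBD-like pattern the simulation encodes: REM
motor activity (0.34 counts/min) well above N2 (0.06) and N3 (0.02).

A reference nine-participant RBD cohort summary (sleep architecture,
per-participant κ, activity burden, pooled overlap regions) ships under
`inst/extdata/` and is available via `reference_cohort()` for worked
examples and checks.

A thin command-line front end over the same functions lives at
`inst/cli/remmotor.R` (`simulate`, `counts`, `score`, `concord`, `stats`,
`run-all`).

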