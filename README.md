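# frpmap

Analysis of the **flexion relaxation phenomenon** (FRP) from high-density
surface EMG (HDEMG) of the lumbar paraspinal muscles.

During slow trunk flexion the paraspinal muscles of pain-free people fall
electrically silent as the trunk approaches full flexion; in many people
with low back pain (LBP) this relaxation is absent or delayed. `frpmap`
implements the full analysis chain for HDEMG flexion trials — from raw
13 × 5 electrode-grid recordings and a trunk goniometer trace to
topographic onset maps, normalised amplitude curves, and group inference —
for researchers in neuromuscular physiology and spine biomechanics.

## What it computes

* **Grid model** — 13 × 5 electrodes (8 mm spacing, one corner absent),
  differenced along columns into 59 single-differential (bipolar) channels
  on a 12 × 5 lattice.
* **Preprocessing** — zero-phase Butterworth band-pass (20–350 Hz),
  channel quality screening (task SNR and pre-filter low-frequency power),
  rectified 50 Hz low-pass amplitude envelopes.
* **Kinematics** — segmentation of each repetition into quiet standing,
  flexion, full flexion (MVF) and extension from the goniometer trace
  (velocity-threshold events, plateau tolerance band).
* **FRP onset** — per channel, the first sample of the flexion phase at
  which the envelope drops below `baseline mean + 3 SD` of quiet standing
  and stays there ≥ 0.25 s, expressed as % of trunk flexion; subject-level
  FRP presence when > 50 % of usable channels show an offset; repetition
  averaging and side pooling; topographic onset maps.
* **Amplitude** — grid-mean RMS over twelve 1-s epochs (4 flexion + 8
  MVF), normalised to the peak 1-s grid-mean RMS of the extension phase.
* **Inference** — mixed-effects smoothing-spline ANOVA, written in-package:
  a 2D thin-plate smooth over channel position for the onset map and a 1D
  cubic smooth over epoch time for the amplitude curve, nominal group (and
  side) factors, subject random intercepts, GCV-selected penalties, and
  Bayesian 95 % confidence intervals for pairwise group contrasts. A
  contrast is significant when the interval of its grid-averaged mean
  difference excludes zero.
* **Synthetic cohorts** — a generator with known per-channel onset truth
  (three groups: controls relax mid-flexion, one LBP subgroup relaxes
  late, one never relaxes), used to validate the whole chain by parameter
  recovery.

## Worked example

Simulate a small cohort and run the full analysis (a reduced sampling rate
keeps the example quick; the defaults mirror a 2048 Hz acquisition):

```r
library(frpmap)

cfg <- synthetic_config(
  n_per_group = c(control = 14, lbp_frp = 9, lbp_no_frp = 5),
  sampling_rate = 512, noise_band = c(20, 220),
  n_repetitions = 1, sides = "R", seed = 11)
cohort <- generate_cohort(cfg)

res <- analyze_cohort(cohort, pipeline_config(filter_band = c(20, 220)))
res
#> FRP analysis results
#>   subjects: control=14, lbp_frp=9, lbp_no_frp=5
#>   FRP prevalence among LBP: 64.3%
#>   onset Contrast lbp_frp - control: mean difference 15.54 (95% CI 11.58 to 19.51) *
```

All 14 controls are classified FRP-present, 9 of the 14 simulated LBP
subjects show the FRP (64.3 % prevalence), and the onset contrast reports
the delay of the LBP-with-FRP group relative to controls in percent of
trunk flexion, with its 95 % Bayesian interval (the generator injected a
13 % mean delay; this cohort's realised subject means differ by 15.6 %, and
the estimate tracks the realised truth). Against the generator's
channel-level truth:

```r
rec <- onset_recovery(res, cohort$truth)
attr(rec, "bias"); attr(rec, "rmse")
#> [1] 1.26      # mean error, % of trunk flexion
#> [1] 1.31      # per-subject RMSE, % of trunk flexion
```

Amplitude contrasts and figures:

```r
res$amplitude_contrasts[["lbp_no_frp vs control"]]
#> Contrast lbp_no_frp - control: mean difference 48.85 (95% CI 47.87 to 49.84) *
plot_amplitude_curves(res)   # group mean +/- SD across the 12 epochs
plot_onset_map(res)          # group-averaged topographic onset map
run_report(res, "report", truth = cohort$truth)  # tables + figures on disk
```

File-based workflows mirror the same steps: `run_simulate()` writes a
cohort as delimited trial matrices with YAML sidecars, `run_analyze()`
processes a directory, `read_trial()`/`write_trial()` handle single
recordings.

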