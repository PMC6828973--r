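---
title: "Mapping the flexion relaxation phenomenon from high-density EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the flexion relaxation phenomenon from high-density EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frpmap)
```

## The problem

During slow trunk flexion the superficial lumbar paraspinal muscles of
healthy people fall electrically silent once the trunk approaches full
flexion — the flexion relaxation phenomenon (FRP). In many people with low
back pain (LBP) this relaxation is absent, and when it is present it can be
delayed. Classical bipolar surface EMG samples one location per muscle and
has produced famously variable estimates of both facts. High-density
surface EMG (HDEMG) records from a grid of closely spaced electrodes — here
13 rows × 5 columns, 8 mm apart, one corner electrode absent as a
directional reference — and turns the question into a spatial one: *where*
on the muscle, and *when* during flexion, does each recording site switch
off?

`frpmap` implements the full analysis chain for such experiments: grid
geometry and monopolar→bipolar derivation, channel quality screening,
zero-phase filtering and envelope extraction, goniometer-based phase
segmentation, per-channel detection of the EMG offset, topographic onset
maps with a subject-level presence rule, epoch-wise amplitude profiles
normalised to the extension-phase peak, and smoothing-spline ANOVA
(SS-ANOVA) group inference with Bayesian confidence intervals. Because raw
recordings of this kind are rarely shareable, the package also contains a
synthetic-cohort generator with known ground truth; every stage of the
pipeline is validated against that truth or against an independent oracle.

## The task and its segmentation

Each repetition is a trapezoidal task: quiet standing, ~4 s of trunk
flexion, ~8 s of sustained full flexion (MVF), ~4 s of extension back to
neutral. A single-channel electrogoniometer trace is segmented by:

* **flexion start** — first sample at which the smoothed angular velocity
  exceeds a fraction (default 5%) of the peak flexion velocity;
* **flexion end / MVF start** — first sample at which the angle enters and
  stays within `angle_tol` (default 2°) of the maximal flexion angle;
* **extension start** — the symmetric event on the descending limb;
* **baseline** — a 1-s quiet-standing window ending 0.5 s before flexion
  start.

These event rules are not unique — the source experiments typically do this
semi-automatically by eye — so every threshold is exposed in `seg_config()`.
Two consequences of the tolerance-band rule matter downstream. First, the
detected flexion phase is systematically a fraction of a second shorter
than the nominal 4 s (the last 2° of range take ~0.1–0.2 s at typical
angular velocity); empirical flexion durations in this literature
(3.5–3.9 s) show the same. Second, because of that trimming the package
counts amplitude epochs by *rounding* the detected phase duration to whole
seconds rather than truncating: a detected 3.85-s flexion phase still
yields the nominal 4 one-second epochs, tiled contiguously from flexion
start. Genuinely short phases still produce fewer epochs, with a warning.

## Preprocessing

Monopolar signals are band-pass filtered (Butterworth, 20–350 Hz corner
frequencies, 4th order) and differenced between cranio-caudally adjacent
electrodes within columns — the fibre direction — giving 59 bipolar
channels on a 12 × 5 lattice for the default grid (a 13 × 5 grid with one
absent corner). The difference is taken caudal minus cranial; the absent
corner removes exactly one adjacent pair.

All filtering is zero-phase: the forward–backward Butterworth response
(the squared magnitude) is applied in the frequency domain after odd
reflection padding. This is numerically identical to time-domain
forward–backward filtering away from the trial edges (a unit test holds it
to < 1e-9 against `signal::filtfilt`) and vectorises across channels, which
is what makes whole-cohort simulation studies affordable. Zero phase
matters because any filter group delay would bias every timing estimate.

The onset detector runs on the amplitude envelope: full-wave rectification
followed by a zero-phase 50 Hz Butterworth low-pass.

### Quality screening

The source experiments exclude channels with poor signal quality by visual
inspection. The automated stand-in uses two per-channel statistics:

* **task SNR** — band-limited RMS over the active window divided by RMS
  over the quiet-standing baseline; channels below `snr_min` (default 3)
  are flagged `low_snr`;
* **low-frequency power fraction** — fraction of *pre-filter* bipolar power
  below the 20 Hz band edge; channels above `artefact_max` (default 0.5)
  are flagged `artefact`. Movement artefact is common mode across the grid
  and cancels in a clean bipolar pair, so a large low-frequency residue
  indicates a faulty electrode contact breaking that cancellation.

Flagged channels are kept with reason codes, never deleted: maps show holes
exactly where channels were excluded, and excluded channels leave the
denominator of the presence rule.

## FRP onset detection

The per-channel EMG offset is defined against quiet standing: with baseline
envelope mean μ and standard deviation σ, the threshold is μ + kσ
(default k = 3). The onset is the *first* sample within the flexion phase
at which the envelope falls below the threshold and stays below it for at
least `hold_s` (default 0.25 s, the debounce a visual analyst applies
implicitly); later re-activation does not retract the detection. A channel
whose envelope never satisfies the rule during flexion has no FRP. A
channel already below threshold at flexion start is reported as present at
0% with a `never_active` diagnostic. The detector is verified
sample-exactly against an exhaustive brute-force scan in the test suite.

The threshold direction deserves a note: "below three standard deviations
of the baseline mean" is implemented as *below μ + 3σ* — the standard
activity-detection threshold. μ − 3σ would be unreachable for the tonic,
never-zero envelope of postural paraspinal muscles.

Onsets are expressed as percent of trunk flexion. The default axis is the
**angle** axis (percent of the maximal flexion angle at the onset sample);
a **time** axis (percent of elapsed flexion-phase time) is available in
`det_config()` for sensitivity analysis, since published wording rarely
distinguishes the two.

At the subject/side level the FRP is *present* when strictly more than 50%
of non-excluded channels show an offset during flexion. Channel onsets are
averaged across the three repetitions (presence by per-channel majority,
ties counting as present), and sides are pooled by averaging after a paired
side-difference check that warns — but does not block — when sides differ.

## Amplitude profiles

Per epoch (1-s windows, 4 flexion + 8 MVF), the RMS of each usable bipolar
channel is computed and averaged across the grid; each epoch value is then
normalised to the peak grid-mean RMS over the 1-s windows of the extension
phase — extension re-activation is reliably the strongest activity in the
trial, making it a stable within-trial reference. The epoch-level peak (not
the instantaneous envelope peak) keeps the reference on the same footing as
the values it scales. Normalised profiles are invariant to any overall
channel gain.

## SS-ANOVA inference

Two models quantify group differences:

* **onset ~ space** (2D): response is the per-channel onset percent; the
  smooth is a thin-plate spline (kernel r² log r, affine null space) over
  the channel positions in mm; group (LBP-with-FRP vs control) and side are
  nominal factors; group-specific smooth and affine deviations let the
  spatial pattern differ by group; a subject random intercept absorbs
  between-subject shifts.
* **amplitude ~ time** (1D): response is the normalised epoch amplitude;
  the smooth is a cubic spline (kernel |r|³, linear null space) over the 12
  epoch midpoints; group (three levels) is nominal, with the same deviation
  and subject structure.

The solver uses a representer radial basis on at most 100 knots (the
unique axis locations here: 59 channel positions, 12 epoch midpoints),
with the penalty projected onto the complement of the polynomial null
space, so an exact line or plane is reproduced with zero penalty at any
smoothing weight. Each penalised term — the shared smooth, the pooled
group-deviation smooths, and the subject ridge — carries its own weight
selected by generalised cross-validation (GCV, `n·RSS/(n − tr H)²`) via
coordinate descent over a log grid spanning 14 orders of magnitude,
followed by local golden-section refinement that is only kept when it does
not lose to the best grid point.

Uncertainty follows the Bayesian reading of the roughness penalty as a
Gaussian prior: the posterior covariance of the coefficients is
σ²(XᵀX + Λ)⁻¹ with σ² = RSS/(n − tr H), and any linear functional of the
fit — a fitted value, a group difference at a point, the grid-averaged
group difference — gets a t-interval with n − tr H degrees of freedom.
Group contrasts evaluate the difference of the two group curves/surfaces
on the training grid; the difference cancels the intercept, the shared
smooth, the other factors (held at reference) and the subject effects by
construction. A contrast is significant when the 95% interval of its
grid-averaged mean difference excludes zero. Pointwise spline intervals
are known to hold their nominal level *on average across the function*
rather than pointwise; the test suite checks exactly that property
(90–98% average coverage in simulation).

## The synthetic cohort generator

`synthetic_config()` encodes the study conditions: three groups (default
14 controls / 9 LBP with FRP / 5 LBP without), a 2-s quiet-standing
baseline followed by the 4/8/4-s trapezoid, maximal flexion angles drawn
from N(91.2°, 12.4°), true onset means of 55% (controls) and 68%
(LBP-with-FRP) of trunk flexion with 5% between-subject SD, a cranio-caudal
onset gradient (cranial channels later) of 0.5%/row for the LBP-with-FRP
group and none for controls, and 1.5% per-electrode jitter.

Signals are band-limited Gaussian carriers (20–350 Hz at the default
2048 Hz) multiplied by amplitude envelopes. Carriers are partially shared
across the grid (half the variance by default) so that bipolar derivation
*cancels* rather than inflates common components, as on real skin.
Envelopes rest at 10% of the active amplitude during quiet standing
(paraspinals are postural, never silent), rise at flexion start, and — for
channels with an FRP — drop along a 150 ms sigmoid that *completes at the
channel's true onset time*: the true onset is defined as the attainment of
myoelectric silence, which is also (by the μ + 3σ construction) where the
detector's threshold crossing lands. True onsets are specified on the
angle axis and mapped to time through each subject's own angle trace.
Extension re-activates every channel at 1.5× the active amplitude, placing
the normalisation reference in the extension phase. A bipolar channel's
ground truth is the *later* of its two electrodes' onsets — the difference
signal only reaches baseline when the second electrode goes quiet.

`inject_channel_faults()` adds what quality control must catch: a grid-wide
common-mode low-frequency drift (movement artefact) plus a chosen fraction
of electrodes replaced by near-zero signal (lost contact) or a large
independent low-frequency artefact. Clean bipolar pairs cancel the drift
exactly; pairs touching a faulty electrode leak it and are flagged by the
low-frequency power fraction.

What the generator does **not** emulate: motor-unit structure, volume
conduction, electrode impedance, heteroscedastic or non-Gaussian noise,
fatigue-related spectral compression, or between-subject variability in
*amplitude* (only timing varies between subjects). Passing the recovery
tests therefore shows the chain is correct and well calibrated under the
assumed signal model — not that it is robust to every pathology of real
recordings; the QC and segmentation stages carry the configurable
thresholds a real study would tune.

## Workflow interface

The pipeline is driven from R functions rather than a shell tool, since its
users work interactively: `run_simulate(config, outdir)` writes a synthetic
cohort (delimited trial matrices plus YAML sidecars and truth tables),
`run_analyze(indir, outdir, config)` processes a directory end-to-end and
writes the classification, onset-map, amplitude and contrast tables with a
run manifest, and `run_report(results, outdir, truth)` emits group
summaries, figures and the truth-versus-estimate recovery table. Every
tunable — filter corners, QC thresholds, segmentation and detection
parameters, the onset axis, the confidence level, the GCV grid and the
seed — lives in `pipeline_config()` / `synthetic_config()`, so a whole run
is reproducible from two configuration objects. Stage-level functions
(`derive_bipolar()`, `segment_phases()`, `build_onset_map()`, ...) expose
the same steps individually. Trials that fail a stage are logged in the
manifest and skipped; a run only aborts if a group loses all its subjects.

## Numerical choices and problem sizes

* Butterworth orders: 4th-order band-pass (one-way) and 4th-order envelope
  low-pass; only corner frequencies are prescribed by convention, the order
  is a package default.
* The GCV grid is 10⁻⁶…10⁸; refinement is golden-section on log λ and is
  discarded if it does not improve on the grid optimum. Near-singular
  penalised systems (tiny subject ridge on a saturated design) fall back to
  a jittered inverse.
* Ties in the repetition-majority rule count as present (logged); the
  presence rule itself is strict (> 50%), so a fraction of exactly one half
  is *absent*.
* Simulation-based tests and the acceptance script run at 512 Hz sampling
  (carrier band 20–220 Hz), one side and one repetition — the processing
  chain is sampling-rate agnostic, and these sizes keep the full 25-cohort
  recovery study to a few minutes. `synthetic_config()` defaults remain at
  the full acquisition values (2048 Hz, two sides, three repetitions).
* Degenerate inputs error early with diagnostics: flat angle traces, traces
  that never return toward neutral, baseline windows under 0.25 s,
  all-channel QC failure, zero extension reference.

## Known limitations

* The onset model treats channels within a subject as exchangeable given
  the subject intercept; residual within-grid spatial correlation beyond
  the fitted smooth is not modelled, so spatial intervals are approximate.
* GCV, not REML, selects the subject ridge; with very few subjects per
  group the between-subject variance can be under-penalised.
* The automated QC rule is a stand-in for the visual screening used in
  practice; its thresholds are validated only against the fault model the
  generator produces.
* The FRP presence rule and onset axis follow one published convention;
  both are configurable because conventions differ across laboratories.
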