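---
title: "A calibration-free EEG stress index and its comparators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibration-free EEG stress index and its comparators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostress)
```

## The problem

Stress degrades decision-making and is a key human factor in road safety,
which motivates continuous, unobtrusive monitoring during tasks such as
driving. Classifier-based mental-state monitors need a calibration session
in the target task, which is rarely feasible out of the lab. This package
implements and evaluates a *calibration-free* electroencephalographic
stress index — here called the **Neurometric** — together with the three
comparator measures a validation study would use:

* **Neurometric**: mean band power in a subject-specific high-beta band at
  the parietal electrodes P3 and P4, one value per 1 s epoch. No training
  data are needed; the only subject-specific input is the alpha peak
  frequency measured from one minute of eyes-closed rest.
* **SCL**: the mean tonic skin-conductance level, the classic peripheral
  arousal correlate, derived from electrodermal activity (EDA).
* **RF-intra**: a random forest trained on the same parietal features,
  trained and tested within subject and task across repetitions.
* **RF-cross**: the same model trained on laboratory multitasking data and
  applied to driving — the realistic "calibrate in the lab, use on the
  road" scenario.

All four produce a time-indexed score on a common 1 s epoch grid and are
compared by their ability to separate low- from high-stress episodes
(ROC AUC), at time resolutions from 1 s to 60 s.

## The Neurometric pipeline

EEG is recorded from AFz, AF3, AF4, AF7, AF8, Pz, P3, P4 at 250 Hz
(earlobe reference). Processing order is fixed:

1. **Band-pass filter**: fifth-order Butterworth, 2–30 Hz. Offline the
   filter is applied forward–backward (zero phase); a `causal = TRUE` flag
   reproduces the single-pass behaviour a real-time system would have.
   Signals are de-meaned and reflection-padded before `filtfilt` to avoid
   edge transients.
2. **Blink correction**: blinks are frontal-dominant, so they are detected
   on the smoothed mean of the AF channels by an amplitude threshold
   (default 40 µV) and, inside each detected interval, the frontal-derived
   blink component is regressed out of every channel. This is a deliberate,
   documented simplification of published blink-detection plus
   multi-channel Wiener filtering approaches: the stage is pluggable, and
   only its contract (signal untouched outside detected intervals,
   frontal–parietal blink covariance strongly reduced inside) is relied on.
3. **Epoching**: consecutive non-overlapping 1 s epochs, trailing partial
   second discarded.
4. **Artifact rejection**: an epoch is discarded when any channel strictly
   exceeds ±80 µV at any sample. "Strictly" means an epoch peaking at
   exactly 80.0 µV is kept; the rule is a decision on the raw amplitude,
   samples are never modified.
5. **IAF estimation**: Welch spectrum (2 s Hann segments, 50 % overlap,
   0.5 Hz resolution) of the mean parietal signal of the rest block; the
   Individual Alpha Frequency is the most prominent local maximum in
   7–13 Hz. The prominence floor is 0.5 × the median band density: with the
   ~59 averaged segments a 60 s rest block provides, chance fluctuations of
   a peak-free spectrum stay below this floor, so a flat (noise-only)
   spectrum reliably triggers the documented fallback IAF = 10 Hz, while
   any realistic alpha peak (SNR well above 2) is found. A lower floor
   (e.g. 0.2) makes the fallback path unreachable in practice because
   Welch noise wiggles already exceed it.
6. **Band definition**: Beta High = (IAF + 11) to (IAF + 16) Hz, i.e.
   21–26 Hz for the canonical 10 Hz alpha.
7. **Band power**: per epoch and channel, a Hann-windowed periodogram
   (1 Hz bins at 1 s epochs); power is summed over bins whose *centers*
   fall in the closed interval [lo, hi]. Non-integer band edges use the
   same bin-center rule — deterministic rather than interpolated. The Hann
   window is periodic, so a DC offset cannot leak past the first bin and
   band power is offset-invariant.
8. **Neurometric**: the row-wise mean of the P3 and P4 band-power columns.

The term *Global Field Power* classically denotes the spatial standard
deviation across channels; because the stress index addresses named
channels (P3, P4), this package adopts the per-channel band-power reading
and flags the interpretation here. No per-subject normalization is applied
before AUC (AUC is invariant to monotone transforms); min–max normalization
to [0, 1] is used only when curves are plotted or compared (`normalize_curve`).

## The EDA pipeline

Raw EDA (64 Hz) is decimated to 8 Hz behind an anti-aliasing low-pass,
then low-pass filtered at 2 Hz (fifth-order Butterworth, zero phase).
Fast pressure/motion spikes are detected as samples whose absolute first
difference exceeds a physiological slope ceiling (default 0.5 µS per
sample at 8 Hz) and are replaced by cubic-spline interpolation anchored
outside the interval; the detected intervals and their peak slopes are
returned as a review table — the reproducible stand-in for an expert
visual check. Tonic/phasic separation is a simplified fixed-kernel
deconvolution: a Bateman kernel with rise 0.75 s and decay 2 s (standard
skin-conductance-response constants), Tikhonov-regularized FFT
deconvolution, non-negativity clipping of the driver, and a 10 s centered
moving median for the tonic level. The decomposition contract is
self-consistency: tonic + phasic reconstructs the corrected input within
5 % RMS on clean data; no numerical parity with any particular
deconvolution toolbox is claimed. The SCL measure is the mean of the tonic
trace in each 1 s epoch.

## The random-forest comparators

Features are the P3 and P4 Beta High band powers of every labeled epoch.
Multitask levels 1–2 are labeled low stress, levels 6–7 high stress;
levels 3–5 are excluded from training entirely rather than given invented
ordinal labels. Driving epochs inherit their run's condition.

When artifact rejection leaves the classes imbalanced (minority/majority
ratio < 0.8), ADASYN oversampling restores balance: each minority point
receives a share of the synthetic budget proportional to the fraction of
majority points among its 5 nearest neighbours, and synthetic points are
interpolated on segments towards minority neighbours. Synthetic rows are
flagged and never appear in any test split.

Hyperparameters are tuned by randomized search over the published ranges
(trees 50–500, depth 2–30, minimum split fraction 0.01–0.5, minimum leaf
fraction 0.01–0.5, maximum leaf nodes 2–40), scored by stratified 3-fold
cross-validated AUC *inside the training split only*. The backend is
`ranger`; the leaf-count cap has no direct ranger equivalent and is
enforced as the equivalent depth bound `ceil(log2(max_leaf_nodes))`, and
the two fraction parameters map to `min.node.size` and `min.bucket`.
The default search budget in the cohort runner is 10 draws — with two
features and a few hundred epochs the inner-CV score surface is flat and
larger budgets change nothing but runtime; `model_spec()` defaults to 50
draws for standalone use.

The intra-subject protocol trains on one repetition and scores the other,
for every ordered pair, so each repetition is a held-out set. The
cross-task protocol trains one model per subject on all labeled multitask
epochs and scores all labeled driving epochs.

A note on cross-task fragility: a *common multiplicative* shift of both
features is (almost) a monotone transform of the forest's score, so AUC
survives it. What breaks the cross-task model is a shift that pushes the
driving features outside the training support — the trees saturate, the
probability collapses towards a constant, and discrimination is lost.
The test suite exercises exactly this mechanism.

## Evaluation

Scores are compared by the Mann–Whitney formulation of the ROC AUC (ties
counted ½), computed per evaluation session (one multitask repetition, or
one driving repetition comprising its four runs), then averaged per
subject. Coarser time resolutions are emulated by a trailing moving
average of 1–60 s ("decimation"): trailing because the framing is
real-time, and restricted to same-condition blocks because averaging
across a condition boundary would mix differently-labeled scores. At the
start of a block the window expands from 1 to its nominal length.

Group statistics are nonparametric: Friedman's test on within-subject
ranks across measures (per decimation), Dunn's pairwise Z on mean ranks
gated on Friedman significance at α = 0.05 (per decimation, unadjusted by
default with a Bonferroni option), and Wilcoxon signed-rank tests for
paired low/high comparisons of performance, collision and questionnaire
scores (exact p below n = 10 without ties, normal approximation with
continuity and tie correction otherwise; zero differences are dropped).
When every within-subject ranking is fully tied, the Friedman statistic is
0 and p = 1 by convention. Curve similarity is summarized by Pearson R and
RMSE on min–max-normalized curves matched on the common epoch grid.

## The synthetic cohort

No public recordings exist for this paradigm, so the package ships a
generator that produces complete subjects with the statistical structure
the analysis assumes, and the whole pipeline is validated end-to-end on
synthetic cohorts. Per subject: one 60 s eyes-closed rest block, two
repetitions of the seven 60 s multitask levels, and driving runs
(2 scenarios × low/high × 2 repetitions, 60 s each). Two battery
repetitions are generated because the intra-subject protocol needs a
train/test split; the driving run structure likewise makes ordered
train/test pairs possible.

The EEG model is: 1/f background noise (7 µV SD per channel), a
parietal-dominant alpha rhythm at the subject's true IAF (6 µV at rest,
2 µV during tasks, with slow phase jitter — narrowband components were
chosen over a fitted spectral model to keep peak location and effect size
controllable), and a narrowband high-beta component on P3/P4 centred at
IAF + 13.5 Hz, i.e. the centre of the Beta High band, so it stays inside
the band even with IAF estimation error up to 2 Hz. Its per-epoch
log-amplitude is Gaussian with SD 0.4; the stress effect shifts it by
`beta_effect × 0.4 × (stress − ½)`, which — because band power is
amplitude squared and the background contribution to the band is kept
below ~10 % — realizes a standardized log-power difference close to
`beta_effect` between high and low conditions. The default
`beta_effect = 1.5` yields epoch-level AUC ≈ 0.85 and ≈ 0.99 after 60 s
decimation, the operating regime the validated measure reports. Blinks are
400 ms positive deflections (~110 µV frontal, ×0.2 parietal) at 8/min;
amplitude artifacts >80 µV occur at 2/min.

The EDA model is a tonic level (default 5 µS) plus a smoothed random-walk
drift (0.015 µS per 64 Hz sample before smoothing), a stress shift
(default +1 µS), Bateman-shaped phasic responses (more frequent under
stress) and fast ±2 µS square spikes. Because AUC is scale-invariant and
the drift is the only within-session variability of the tonic level, SCL
discrimination is strong but variable across subjects (AUC ≈ 0.85–1.0) —
qualitatively the high-dispersion behaviour expected of a slow peripheral
measure. Stress levels for the seven multitask levels ramp 0, 0, ¼, ½, ¾,
1, 1 so that middle levels are genuinely intermediate.

Behavioral generators produce subtask counts and reaction times whose
expected overall performance decreases with level, driving collision logs
as Poisson event streams (higher rate under stress) interleaved with
non-collision events, and NASA-TLX subscale scores shifted by condition.

What the generator does *not* emulate — and therefore what passing tests
do **not** show about real data: real EEG morphology beyond band-power
structure, non-blink ocular and muscle artifacts, electrode drift,
between-task changes of the feature distribution (the cross-task tests
impose those shifts explicitly), thermoregulatory EDA confounds, and any
true coupling between behaviour and physiology beyond the shared stress
drive.

## Study conditions and problem sizes

The default cohort is 18 retained subjects with seeds 1–18 (a 30 %
rejected-epoch quota can exclude heavily artifacted subjects from cohort
statistics, mirroring attrition in real cohorts; at the default artifact
rates all 18 are retained). The headline checks run the full Neurometric
pipeline on this cohort and verify AUC > 0.9 at 60 s decimation in both
experiments and a median AUC non-decreasing in the decimation window. The
null-calibration check regenerates 20 subjects with no stress effect in
either modality (`beta_effect = 0` and `scl_stress_shift = 0` — a null
EEG effect alone would leave the SCL comparator non-null) and verifies
that each measure's AUC, pooled over tasks, repetitions and the decimation
grid, lies in [0.45, 0.55]. Pooling is the honest summary here: under the
null the tonic drift is the only SCL signal and per-session AUC is nearly
uniform, so any single cell is noisy while the pooled mean concentrates.

## Known limitations

* The blink and EDA-decomposition stages are simplified substitutes with
  stated contracts, not reimplementations of the published algorithms.
* Welch resolution bounds IAF accuracy at ±0.25 Hz plus noise; the band
  placement tolerates this by construction.
* The generator's stress effect is stationary within a block; real stress
  dynamics (onset lag, habituation) are not modelled, which flatters the
  block-wise AUC slightly at long decimations.
* `max num of additions/entries` is read as the subject's maximum across
  the seven levels (per-subject reading); a per-level reading would change
  the two count-based indices by a constant factor per level.
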