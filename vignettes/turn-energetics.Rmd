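---
title: "Estimating turn energetics and kinematics from a pelvis-worn inertial unit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating turn energetics and kinematics from a pelvis-worn inertial unit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codwork)
```

## The problem

Repeated 180-degree changes of direction (CoD) are among the most demanding
actions in team sports: each turn requires braking the whole-body centre of
mass (CoM), lowering it, reversing it, and re-accelerating, all in about a
second. Laboratory practice quantifies each turn with five targets derived
from optical motion capture:

* the mass-specific **positive and negative external mechanical work**
  `W+`/`W-` (J/kg) performed on the CoM over a 2 s window around the turn,
* the mean CoM **approach and exit speed** `v_before`/`v_after` (m/s) over
  the second before and after the turn, and
* the **pivot side** (left or right).

Motion capture is confined to the laboratory. `codwork` implements a
field-ready alternative: a single six-axis inertial unit with a barometer,
worn at the pelvis, from which 18 per-turn features are extracted and fed
to standard regression and classification models trained against the
mocap-derived targets.

## The model

### External energy and work

With `v` the norm of the CoM velocity and `h` its height, the mass-specific
external mechanical energy is

$$E_{ext}(t) = \tfrac12 v(t)^2 + g\,h(t), \qquad g = 9.81\ \mathrm{m\,s^{-2}}.$$

Over the 2 s turn window, `W+` is the sum of positive sample-to-sample
increments of `E_ext` and `W-` the magnitude of the negative ones, so that
`W+ - W- = E_ext(end) - E_ext(start)` holds exactly on every window (this
telescoping identity is asserted in the test suite). `W-` is reported as a
magnitude; a dissipative turn therefore has both `W+ > 0` and `W- > 0`.

Positions are low-pass filtered before differentiation (zero-lag 2nd-order
Butterworth, 15 Hz cut-off, applied forward-backward) and velocities come
from central differences of the filtered trajectory. Turn events are the
alternating extrema of the CoM coordinate along the lane, with a minimum
spacing of 1.5 s — comfortably between the step period (~0.35 s) and the
shuttle period (~2 s) — so step-level wiggles are never mistaken for turns.

When only a 14-marker set is available, the CoM is built by the segmental
centroid method: segment centroids from marker pairs, combined with Dempster
mass fractions (head 0.081, trunk 0.497, upper arms 0.028, forearms+hands
0.022, thighs 0.100, shanks+feet 0.061 per side; they sum to one).

### The inertial side

The sensor frame has x pointing backward, y up and z to the subject's left.
Static biases are estimated as channel means of a still recording and
subtracted; by default the estimate includes the gravity reading on the
vertical axis, which puts the in-motion acceleration norm on a near-zero
baseline between foot strikes (set `gravity_compensate = TRUE` in
`estimate_static_bias()` to keep gravity in the corrected signals). The six
inertial channels are then low-pass filtered (zero-lag 4th order, 128 Hz).

Turns are detected on the IMU clock as peaks of the absolute value of the
0.5 Hz zero-lag-filtered yaw rate (`gy`): a 180-degree reversal leaves a
smooth, prominent pulse there. The two clocks are aligned by
cross-correlating Gaussian-smoothed impulse trains of the candidate event
times from both systems on a common 100 Hz grid; the argmax lag is the clock
offset. Impulse trains rather than raw signals make the correlation
insensitive to the very different shapes of the two carriers (triangle-like
lane position vs. pulse-like yaw rate).

The 18 features per synchronized 2 s window are: player load (cumulative
norm of consecutive acceleration differences, computed on g-scaled
accelerations per the accelerometry convention, F1); trapezoidal integrals
of the positive and of the negative part of each accelerometer axis
(F2-F7, SI units); RMS, skewness and kurtosis of the acceleration norm
(F8-F10); the three gyroscope integrals after deg-to-rad conversion
(F11-F13); RMS, skewness and kurtosis of the gyroscope norm (F14-F16); and
the barometric altitude change over the second before and after the event
(F17, F18), from pressure low-pass filtered at 1 Hz (zero-lag 10th order)
and converted to altitude by the international barometric formula
`h = 44330 (1 - (p/p0)^{0.1903})`. Skewness and kurtosis are population
moments (denominator n, kurtosis of a Gaussian = 3, no excess correction).
The pivot side is the sign of the net yaw rotation over the window
(positive = left in this frame).

Before modelling, a turn is discarded when any response or feature falls
outside its column mean ± 3 SD (computed once, not iterated), and the
coefficient of variation SD/|mean| is reported per variable, flagged not
applicable for bimodal variables whose CV exceeds 50 (e.g. signed gyroscope
integrals, whose mean sits between two well-separated modes).

### Models and validation

Four regression families predict each continuous response from the 18
features: multiple linear regression, support-vector regression with a
Gaussian kernel, least-squares boosted trees (40 learners), and a
single-hidden-layer neural network (40 units). Four classifiers (linear
discriminant analysis, Gaussian-kernel SVM, boosted trees, neural network)
predict the side. All except the network are evaluated by seeded 10-fold
cross-validation with metrics pooled over held-out predictions (R², RMSE,
MAE; accuracy, sensitivity, specificity, AUC with left as positive class).
The network uses a single 70/15/15 train/validation/test split with
validation-based early stopping, reported on the test portion; a `"cv"`
mode routes it through the same k-fold scheme instead.

Unstated hyperparameters were fixed as: SVR tube ε = 0.1·SD(y) and kernel
width by the median heuristic (recorded in the evaluation object); boosting
learning rate 0.1 and depth 4; network weight decay 1e-3, trained in chunks
of 100 epochs for at most 8 chunks keeping the best validation weights.
The hidden units use the logistic sigmoid of `nnet`, affine-equivalent to a
tanh layer. Boosted trees also report split-gain feature importance,
normalized to sum to one.

Folds are plain random partitions of turns. Pooling turns across subjects
lets fold-mates share a subject, which flatters pooled-turn
cross-validation; grouping folds by subject would be the stricter protocol,
and the per-subject `subject` column in the processed table makes that easy
to add, but the plain partition is kept as the default deliberately to
match the evaluation design this package reproduces.

## The synthetic shuttle-run generator

No recordings ship with the package; every stage is instead exercised on
synthetic trials with known ground truth. The generator emulates a 5 m
shuttle run at a 2.5 m/s average pace with alternating 180-degree turns:

* **Lane profile.** Constant-speed cruise legs joined by raised-cosine
  velocity reversals of 0.9 s, so position, velocity and acceleration are
  continuous and available in closed form. Because the reversal covers less
  ground than cruising, legs are run at ~3.0 m/s to hold the 2.5 m/s pace —
  which is also why the approach speed averaged over the second before the
  turn (2.60 m/s) sits above the nominal pace.
* **Vertical profile.** A raised-cosine CoM dip of 0.375 m (half-width
  0.8 s) centred on each turn, plus a 8 mm step oscillation at 2.9 Hz.
* **Lateral profile.** A 0.20 m arc through each turn, signed by the pivot
  side, plus a small stride-frequency sway.
* **Sensor model.** The accelerometer reads the rotation of the specific
  force into the (yaw-following) sensor frame plus Gaussian-windowed foot-
  strike transients (50 m/s² peak, 5 ms SD, alternating lateral sign);
  the gyroscope reads the Hann-shaped yaw-rate pulse of each turn plus
  gait oscillations; both carry static biases, white noise and (gyro) a
  linear drift. The barometer encodes site altitude plus CoM height through
  the standard atmosphere. IMU and barometer timestamps are shifted by a
  clock offset drawn uniformly in ±2 s, so synchronization is always
  exercised. Per-leg speed (SD 0.15 m/s) and per-turn dip depth (SD 0.05 m)
  jitter within a trial; cohorts additionally jitter each subject's pace
  (SD 0.2 m/s), mass, height and dip.

Ground truth per turn (event time, side, speeds, work) is computed from the
analytic profile on a 1 kHz grid — no filtering, resampling or sensor model
involved — which makes it a genuinely independent oracle for the pipeline.

The free shape parameters (turn duration, dip depth/width, arc radius, step
amplitude, impact size) were calibrated once so that noiseless cohort means
reproduce the reference cohort: approach speed 2.60 m/s, positive work
~8.5 J/kg, barometric deltas ≈ −0.39/+0.39 m, and feature summaries inside
the reference ranges; they are fixed defaults, not tuning knobs. A
13-subject cohort at 72 turns each yields 936 turns, matching the ~937-turn
scale of the emulated study.

What the generator does **not** emulate: within-trial fatigue (the target
pace is stationary per trial), soft-tissue and mounting artefacts,
marker occlusion, magnetometer data, non-180-degree cut angles, and any
mislabelling noise in the side ground truth. Classification on synthetic
cohorts is therefore easier than on real data — the net-yaw feature
separates sides perfectly — so a 100% synthetic accuracy shows the pipeline
is lossless for this signal, not that field data would classify perfectly.
Similarly, the synthetic feature-response relations are cleaner than real
ones, so regression R² on synthetic cohorts exceeds what the emulated study
reports on athletes; only the model ordering (nonlinear ≥ linear on the
speed responses) is expected to transfer.

## Numerical choices

* Zero-lag filtering uses `signal::filtfilt` with odd-reflection padding
  and demeaning; without padding, the 10th-order 1 Hz pressure filter rings
  for seconds at the stream edges on a ~101 kPa offset.
* The event detectors quantize event times to one sample of their stream;
  the synchronizer works on a 100 Hz grid with a 0.1 s Gaussian kernel and
  a ±3 s search bound, and refuses to report a lag when the normalized peak
  correlation falls below 0.2.
* Windows are exactly 2 s (1024 IMU samples); turns whose window or 1 s
  barometric margin is truncated by the recording bounds are dropped and
  counted, as are turns whose net yaw is below 90 degrees (undetermined
  side).
* `moment_stats()` refuses constant windows (σ = 0) rather than returning
  NaN; `regression_metrics()` refuses zero-variance references.
* Determinism: every stochastic step (trial noise, fold assignment, network
  initialization) is seeded through `withr::with_seed`; the same seed gives
  bit-identical trials and evaluation reports. Boosting runs single-thread.

## Problem sizes used in the checks

The packaged tests run the full pipeline on a 13-subject, 72-turns-each
cohort (936 turns) for the classification, recovery and noise-floor checks,
and on smaller cohorts (3-4 subjects, 8-24 turns) for unit-level
properties; these sizes were chosen to mirror the emulated protocol at the
cohort level while keeping unit tests light.

## Worked example

```{r example, eval = FALSE}
library(codwork)

cohort <- simulate_cohort(sim_config(seed = 42), n_subjects = 13)
processed <- process_cohort(cohort)
turns <- remove_outliers(processed$turns)

report <- train_models(turns, k = 10, seed = 1)
tidy(report)

# feature importance of the boosted-trees model for approach speed
autoplot(report$evals$v_before.boosted_trees)
```

## Known limitations

* Pivot side on real data would ideally come from limb kinematics; the
  net-yaw proxy used here is exact on synthetic data but untested against
  human labelling.
* The 3 SD outlier screen is applied to all columns (responses and
  features); applying it to responses only would retain slightly more
  turns.
* Consecutive same-side turns (random direction policy) can merge after
  0.5 Hz smoothing when closer than ~2 s; the alternating default never
  triggers this.
* Feature integrals are reported in SI units (m/s, rad); models are
  invariant to per-feature scaling, but absolute magnitudes are not
  comparable to conventions that sum raw samples without the time step.
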