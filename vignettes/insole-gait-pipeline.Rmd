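---
title: "Seven-event gait segmentation and sarcopenia screening from insole IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seven-event gait segmentation and sarcopenia screening from insole IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolegait)
```

## The problem

Sarcopenia — age-related loss of muscle mass and strength — changes how
people walk: speed drops, stance lengthens, single-support time on the
weaker side shrinks, and left-right timing becomes asymmetric. Those
changes are measurable with a pair of instrumented insoles, each carrying a
3-axis accelerometer and a 3-axis gyroscope sampled at 100 Hz. This package
implements the complete analysis chain from raw bilateral 12-channel
signals to a subject-level screening decision:

1. rule-based detection of the seven gait-cycle events — heel strike (HS),
   opposite toe-off (oTO), heel rise (HR), opposite heel strike (oHS),
   toe-off (TO), feet adjacent (FA), tibia vertical (TV);
2. segmentation of each stride into two (stance/swing) or seven
   (Whittle-style) phases;
3. gait features: 23 spatiotemporal parameters, and 10 descriptive
   statistics per channel per phase (240 two-phase or 840 seven-phase
   columns), plus ZUPT stride-length estimation and 100-point stride
   resampling for sequence models;
4. feature selection: a Welch t-test screen to 50 features followed by
   Shapley-value attribution on a gradient-boosted tree model, keeping at
   most the top 20 features with mean |phi| >= 0.002;
5. classification (linear/RBF SVM, random forest, MLP, 1D CNN, BiLSTM)
   under leave-one-subject-out-per-group cross-validation.

Because clinical insole recordings of sarcopenic gait are not publicly
available, the package ships a synthetic bilateral gait generator with
exact ground-truth annotations; every stage is validated against it.

## Axis and unit conventions

The x axis points along the walking direction, y is mediolateral (so
gyro-y is the sagittal "pitch" rate), z is vertical. Accelerations are in
g and assumed gravity-compensated; angular velocity is in rad/s (readers
convert from deg/s on request). Event indices are 0-based samples; a
stride is the half-open interval `[hs, next_hs)`, so time in seconds is
always `index / sample_rate`.

## The detection rules

All detectors are deliberately simple threshold/extremum rules; every
threshold lives in `detector_config()`.

* **Cycle delimitation.** Gait cycles are first delimited coarsely by the
  swing-phase gyro-y (push-off) peaks, found as local maxima above half the
  global maximum with at least 0.4 s spacing.
* **HS.** Walking-direction acceleration dips sharply just before ground
  contact and then jumps at impact. Between consecutive push-off peaks the
  global minimum of `acc_x` is located; the heel strike is the index with
  the largest first difference of `acc_x` within the 10 samples after the
  minimum (earliest index on ties).
* **TO.** The global maximum of gyro-y inside each HS-to-HS window.
* **HR** at the mid-stance to terminal-stance boundary: after gyro-y has
  been quiescent (|gyro-y| below 0.05 rad/s, the "arming" gate that keeps
  loading-response transients from triggering), the first sample at or
  above 0.25 rad/s. If the threshold is never crossed the stride is
  flagged and the normative 32%-of-cycle anchor is substituted.
* **FA** at the initial-swing to mid-swing boundary: treating the swinging
  foot as a pendulum, its forward acceleration crosses zero at the lowest
  point; the detector takes the first descending zero crossing of `acc_x`
  after toe-off, linearly interpolated and rounded half-up to the nearest
  sample. The crossing is armed only after `acc_x` exceeds a quarter of
  its swing maximum, so near-zero flicker right at the stance-swing
  boundary cannot fire it. Fallback: the 77% anchor, flagged.
* **TV** at the mid-swing to terminal-swing boundary: forward velocity is
  re-integrated from the first in-swing gyro-y zero crossing (where the
  forward speed is taken to be zero) and TV is the first sample after FA
  where that velocity returns to zero. Fallback: the 86% anchor, flagged.

Detected per-foot events are then paired: the contralateral TO and HS
falling strictly inside an ipsilateral stride become oTO and oHS. Strides
with unmatched contralateral events or any ordering violation of
`hs < o_to < hr < o_hs < to < fa < tv < next_hs` are dropped and counted;
flagged strides are excluded from feature extraction. Downstream code
therefore never sees a partial event set.

## The synthetic generator

`simulate_cohort()` emulates the study conditions this pipeline targets: 10
normal and 10 sarcopenic elderly women, one straight walk of four gait
cycles per subject at 100 Hz (80 walking cycles in total), with
anthropometrics drawn per group from published cohort statistics truncated
at three standard deviations.

Each stride is built from piecewise-smooth canonical templates rather than
a full biomechanical simulation — only the detector-relevant morphology
matters for validation:

* forward velocity is zero during stance, rises as a squared sinusoid
  through swing to a peak at FA, descends through the planted TV anchor and
  ends in a small dip-and-impact pattern that gives heel strike its
  acceleration minimum and maximal first difference;
* `acc_x` is the discrete derivative of that velocity, so strap-down
  re-integration recovers the planted velocity (and stride length)
  exactly in the noise-free case;
* gyro-y shows a negative loading transient, a quiescent mid stance, a
  linear ramp that reaches 0.25 rad/s exactly at the HR anchor, a
  cusp-like push-off peak exactly at TO (sharp peaks keep the argmax
  well-localized under noise, as in real push-off transients), a zero
  crossing at the planted integration start and a negative swing lobe;
* the contralateral foot runs the same template half a cycle out of phase,
  with per-side stance fractions implementing the planted stance-time
  asymmetry.

White Gaussian noise (default sd 0.05 g / 0.05 rad/s) is added to every
channel. With noise switched off, every detector recovers its ground-truth
index exactly; the test suite asserts this, and asserts that detection
error grows monotonically along a noise grid.

Group effects are planted as distribution shifts: sarcopenic subjects walk
slower (0.82 vs 1.10 m/s, about 3.5 pooled SD — deliberately a strong,
recoverable effect at 10 subjects per group), with longer stride time,
larger stance fraction, reduced right single support (via a longer left
stance) and a larger left-right stance-time difference. `effect_scale`
interpolates these shifts toward zero for type-I-error checks. The
generator does **not** emulate turning, treadmill gait, stumbles, sensor
drift, magnetometer effects, or realistic inter-stride variability within
a subject; passing tests show the pipeline's internal consistency and its
behavior under planted effects, not clinical performance on real data.

## Feature definitions

The 23 spatiotemporal parameters are cadence; stance, swing, single- and
double-support phase (% of cycle) and time (s) per side; step time per
side; stride length; speed = stride length / cycle time; and the
asymmetries |right - left| of stance phase and stance time. `stance% +
swing% = 100` holds per side by construction. Stride length comes from
strap-down integration with zero-velocity updates: an error-state Kalman
filter (states: position and velocity error) receives zero-velocity
pseudo-measurements whenever the angular-rate RMS over a 0.1 s window
falls below 0.3 rad/s; with no quiescent interval the stride falls back to
uncorrected double integration and is flagged. The per-side step-length
split is not part of the canonical 23 here, since a single insole cannot
resolve it without the contralateral position; this is this package's
convention and is stated rather than inferred.

The 10 descriptive statistics per segment are max, min, sample SD,
absolute sum, RMS, excess kurtosis (normal gives 0), adjusted
Fisher-Pearson skewness, the signed max-to-min gradient
`(max - min) / ((argmax - argmin) / fs)`, the range, and the largest
absolute successive difference. Constant segments define skewness and
kurtosis as 0 and carry a flag. Statistics are computed per stride and
averaged per subject before any subject-level model — pooling strides
first would hide the stride count from the reader and weight subjects
unequally.

## Selection and classification

The t-test screen uses Welch's unequal-variance test by default
(switchable to pooled); ties and zero-variance features (p set to 1) break
by column order. The attribution model is a gradient-boosted tree ensemble
(binary logistic objective, 20 rounds, depth 15, gamma 0.009, subsample
0.98, seeded). Attributions use the path-conditional TreeSHAP algorithm;
the package also ships `shapley_exact()`, a full 2^n subset enumeration of
the Shapley formula, plus the cover-weighted conditional-expectation set
function of a fitted ensemble, and the test suite requires the two routes
to agree to 1e-6 on small models. Importance is the mean absolute
attribution per feature; selection keeps at most the top 20 at or above
0.002. Note the booster computes in float32, so the per-sample efficiency
identity (sum of attributions + base = margin) holds to about 1e-6 .. 1e-5
on deep 20-round models; the suite checks it at 1e-4.

Classifiers follow fixed hyperparameters: SVM gamma 1.0 / C 5.0; random
forest with 50 trees, sqrt-features, minimum leaf 1 (its recorded depth
cap of 30 cannot bind at 18 training subjects and is not enforced by the
backend); an MLP with two tanh hidden layers of 20 units trained 70
epochs. The MLP trains by conjugate gradients (`optim(method = "CG")`);
scaled conjugate gradients is not available in any supported backend, and
the evaluation contract here is accuracy-based, not optimizer-based. The
1D CNN (64 filters, kernel 8, stride 1, max-pool 4/4, dense head, softmax)
and the stacked BiLSTM (64 and 32 units, learning rate 0.0005, dropout
0.2, same dense head) are implemented in plain matrix algebra with
analytic backpropagation — verified against finite differences in the
tests — and trained full-batch with Adam for a default 30 epochs (a
practical budget at 72 training strides; configurable). The dense head
width defaults to 1024 and is configurable. Deep models take the
100-point resampled 12-channel stride tensors, or a feature table treated
as a single-channel sequence.

Evaluation is leave-one-subject-out per group: subjects are sorted within
group and fold *i* holds out the *i*-th pair, so each subject is tested
exactly once and folds never mix a subject between train and test (an
internal assertion enforces this). Feature standardization, the t-test
screen and the Shapley selection are refit inside each training fold;
`pooled_selection = TRUE` reproduces the alternative arrangement in which
selection is run once on all subjects before splitting — that arrangement
leaks test information into selection and is provided only for
comparison. Stride-tensor predictions are aggregated per subject by
majority vote (earliest label on ties).

## Numerical choices and degenerate inputs

* Tie-breaks: earliest index for every argmax/threshold/zero-crossing
  rule; the FA crossing rounds half-up (a midway crossing belongs to the
  sample where acceleration has reached zero).
* The generator refuses strides shorter than 40 samples: the
  dip-and-impact heel-strike morphology occupies the last 5 samples and
  the seven anchors plus the 10-sample HS window need room.
* The HR/FA/TV fallbacks (32%/77%/86% anchors) flag the stride; flagged
  strides are excluded from feature tables and counted.
* Boosted trees on very small cohorts (a handful of subjects) may learn a
  single split or none; selection then returns few or zero features and
  reports it, rather than failing.
* All randomness (noise, anthropometrics, subsampling, network
  initialization, dropout) derives from explicit seeds; cohorts are pure
  functions of the master seed.

## Problem sizes in the test suite

The suite validates at the default study scale — 20 subjects, 80 cycles,
840-column tables, 10 folds — for the detection and pipeline claims, and
at reduced sizes (3 + 3 subjects, tiny network widths) for shape
contracts and gradient checks. The chance-level check permutes subject
labels 20 times and requires the mean subject-level accuracy to lie
within the two-sided 95% binomial band around 50% computed on all
permuted decisions. `scripts/acceptance.R` re-simulates the default
cohort from a command-line seed and reports the event-timing error and
the mean detected HR/FA/TV cycle positions.

## Known limitations

* The waveform templates are stylized; amplitude-domain features (RMS,
  kurtosis, ...) separate groups through the planted kinematic
  differences, not through empirically realistic signal texture.
* Left/right clocks are assumed synchronized; `clock_offset` is carried
  through the data model but the simulator always emits aligned pairs.
* The ZUPT filter models only the walking-direction axis; sensor tilt and
  gravity leakage are outside the generator's physics and therefore
  untested.
* Real cohorts will not match the planted effect sizes; accuracy numbers
  on synthetic cohorts say nothing about clinical accuracy.
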