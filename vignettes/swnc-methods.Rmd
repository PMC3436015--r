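---
title: "Weighted sensor-network fusion for activity recognition under sensor disturbances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted sensor-network fusion for activity recognition under sensor disturbances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swnc)
```

## The problem

Body-worn accelerometer systems for human activity recognition are usually
trained under the assumption that the sensor deployment at run time matches
the deployment at design time. In daily use that assumption fails: sensors
rotate inside loose attachments, get displaced, run out of battery, or drift
out of calibration. A recognition model built on a single sensor can collapse
under such disturbances. This package implements a decision-fusion
architecture — the sensor-weighted network classifier (SWNC) — together with
parametric disturbance models and a repeated-trial evaluation protocol, so
that the robustness of single-sensor and fused recognition can be measured
and compared under controlled, reproducible noise.

## The model

Consider $M$ sensor nodes and $N$ activity classes. The architecture has
three levels.

**Base level.** For every node $m$ and class $n$ a binary one-vs-rest
classifier $c_{mn}$ either *accepts* or *rejects* class $n$ for a window of
sensor-$m$ features. The paradigm is pluggable; the shipped default is a
k-nearest-neighbour classifier whose $k$ is chosen per classifier from an
odd grid by leave-one-out accuracy on its training subset. Each $c_{mn}$
sees its own top-$L$ features, ranked by the one-vs-rest ROC criterion
$|\mathrm{AUC} - 0.5|$ so that anti-correlated features count as
informative, and standardized with training statistics because kNN is
distance-based.

**Node level.** The node is a decision model, not a learned entity. Each
classifier's accuracy rate $\bar R_{mn}$, measured on held-out data, is
normalized into class weights

$$\lambda_{mn} = \frac{\bar R_{mn}}{\sum_{k=1}^{N} \bar R_{mk}},$$

so $\sum_n \lambda_{mn} = 1$. An accepting classifier votes
$y_{nq} = \mathbf{1}[q = n]$; a rejecting classifier votes, under the
default *complement* encoding, $y_{nq} = \mathbf{1}[q \neq n]$ — it lends
its weight to every class except its own specialization, so rejection is
informative. The node output over classes is
$O_{mq} = \sum_n \lambda_{mn} \, y_{nq} \in [0, 1]$ and the node decision is
$\arg\max_q O_{mq}$.

**Network level.** Node accuracies $\bar R_m$ (multiclass, held out) are
normalized the same way into node weights $\mu_m$, and the network output is
$O_q = \sum_{m} \mu_m O_{mq}$, decided again by argmax. With uniform
$\lambda$ and $\mu$ the whole construction provably reduces to plurality
voting over base acceptances, which the test suite checks against direct
counting.

### Vote-encoding ambiguity

The rejection encoding admits a second reading in which a rejecting
classifier simply abstains (votes all zeros). The complement reading is the
default because it is the only one under which every entity collaborates in
every decision; the abstain variant is retained behind
`swnc_config(encoding = "abstain")` and kept under test, since switching
encodings is a one-line strategy swap.

### Training protocol

`swnc_fit()` splits its training windows into three equally-sampled
stratified subsets: subset A trains the $M \times N$ base classifiers
(feature ranking included, so selection never sees evaluation data), subset
B yields the $\bar R_{mn}$ for $\lambda$, and subset C yields the $\bar R_m$
for $\mu$. A p-fold cross-validation mode (`weight_mode = "cv"`, default
$p = 10$) replaces the two holdouts with cross-validated averages and trains
the final classifiers on all training windows; it is the better choice when
training data is scarce, at p times the cost. Holdout is the default because
the evaluation protocol repeats the entire fit 20–100 times, which already
averages the split noise.

## Disturbance models

**Rotational noise** models re-orientation of the sensor's local frame by an
Euler rotation $R(\varphi, \theta, \psi)$ about the X, Y and Z axes. For
biaxial sensors the third raw channel is identically zero, so the rotated
signals are the first two components of $R \,(x, y, 0)^\top$:

$$x_{rot} = c(\theta)c(\psi)\,x - [c(\varphi)s(\psi) - s(\varphi)s(\theta)c(\psi)]\,y$$
$$y_{rot} = c(\theta)s(\psi)\,x + [c(\varphi)c(\psi) + s(\varphi)s(\theta)s(\psi)]\,y$$

The matrix is checked to be in $SO(3)$ to $10^{-12}$, and the biaxial
shortcut is verified against the full three-dimensional mapping — the
shortcut is *defined* as that restriction, which keeps the two routes
consistent to float precision. A notable degeneracy: at
$\theta = 90^\circ$, $x_{rot} = \sin(\varphi - \psi)\, y$ — the X channel
becomes a scaled copy of the Y channel and carries no information about the
true X signal.

The severity knob is a single maximum angle: each of $\varphi, \theta, \psi$
is drawn independently and uniformly from $[0, \angle_{max}]$. Uniform is
the minimal assumption for an "arbitrary" re-orientation. Two granularities
are provided: fresh angles per window (default; a loose, shifting
attachment) or one draw per run (a fixed misplacement). Degrees are used at
every interface and converted to radians at a single internal point.

**Additive noise** models displacement, uncalibration, battery faults and
similar anomalies as zero-mean white Gaussian noise of standard deviation
$\sigma$ quoted in mG, applied independently per sample and per axis.
$\sigma = 0$ is a bit-exact no-op.

The two families are deliberately never combined in one disturbance
specification, and disturbances are applied to **test windows only** — the
trained system is assumed to predate the anomaly. Disturbed (window, sensor)
cells carry a provenance flag so the evaluation protocol can prove that
training data stayed clean.

## The synthetic scenario

No public dataset ships with the package; `default_scenario()` generates a
study design emulating a classic wearable setup: 20 subjects, five biaxial
accelerometers (right hip, dominant wrist, non-dominant arm, dominant ankle,
non-dominant thigh) and nine activities (walking, running, cycling, sitting,
standing still, lying down, stretching, strength-training, climbing stairs).

Each window is gravity projection + jittered harmonic oscillation + Gaussian
floor noise:

* **Static components are kept.** Signals are deliberately not high-pass
  filtered; sedentary postures differ mostly in their static gravity
  orientation, which is exactly the component a rotation corrupts (a rotated
  hip sensor can read "standing" as "lying").
* **Dynamics** use a per-activity fundamental frequency (0 for postures,
  0.5–2.8 Hz otherwise) with up to three harmonics of decaying amplitude
  and random phases; amplitudes are placement-specific and scaled by a
  mobility factor below 1 for the motion-limited hip and thigh.
* **Inter-subject variability** is one log-normal amplitude multiplier per
  (subject, placement), log-sd 0.15, applied consistently to all of a
  subject's windows.
* **Defaults**: 50 Hz sampling, 6 s windows (300 samples), 4 windows per
  (subject, activity), 20 mG sensor noise floor, 10–20 % amplitude jitter.
  Sampling rate and window overlap are configuration, not fidelity claims;
  50 Hz is a common wearable rate that keeps a full study on one desktop
  CPU.

What the generator does **not** emulate: biomechanically realistic motion,
transitions between activities (segmentation is assumed given), triaxial or
gyroscope channels, autocorrelated sensor noise, or activity-dependent
posture errors. Passing robustness tests on this scenario therefore
demonstrates the *mechanics* of the fusion and noise machinery — weight
estimation, degradation trends, fusion resistance — not field performance on
real recordings.

## Evaluation protocol

For every repetition: a fresh stratified 70/30 train/test split, a model
fitted on the clean training windows, and test windows of the disturbed
sensors transformed at every level of the grid (level 0, the clean baseline,
is always included and is bit-exact). Single-sensor curves use node-level
decisions of one-sensor models; fusion curves disturb a freshly drawn random
subset of $S$ sensors per repetition and level. `run_sweep()` shares one fit
and one disturbance realization per repetition across all curves, which
makes the fusion-vs-single comparisons paired and keeps a 20-repetition
full-factorial study under ten minutes on one CPU; it recomputes everything
deterministically from one master seed (repetition $r$ seeds the generator
with `seed + r`), so no resume/checkpoint machinery is needed. Default
grids are 0–180° rotations and 0–500 mG, embedding the commonly discussed
15°/30°/90° and 200/500 mG levels.

Accuracy is plain multiclass accuracy; curves report mean ± standard
deviation over repetitions. The test suite uses 20 repetitions and reduced
grids ({0, 15, 30, 90}° and {0, 100, 200, 500} mG); the acceptance script
uses 10 repetitions. Statistical assertions (monotone degradation, fusion
dominance) are made within two pooled standard errors at those sizes.

## Numerical choices

* Argmax ties — at node and network level — break to the lowest class
  index; kNN distance ties break by training-row index; with odd $k$ a
  binary vote cannot tie. Prediction is therefore fully deterministic, which
  is why a small internal kNN is used rather than an off-the-shelf routine
  that randomizes ties (the off-the-shelf routine serves as a cross-check in
  the tests).
* Node scores are clamped to $[0, 1]$; the algebra guarantees the bounds and
  the clamp only removes $10^{-16}$-scale float overshoot.
* Constant features get unit scale during standardization; the correlation
  feature of a constant axis is defined as 0; spectral features exclude the
  DC bin. Every feature is total on finite windows, and extraction fails
  loudly naming any feature that produces a non-finite value.
* Weight normalization requires a positive accuracy sum; an all-zero
  accuracy vector raises a degenerate-weights error rather than silently
  producing NaN weights.

## Known limitations

* With a **majority of sensors heavily disturbed by additive noise**
  (e.g. $S \ge 4$ of 5 at 200–500 mG), the robustness sweep on the default
  scenario shows fused accuracy falling to chance and below the average
  disturbed single sensor. The mechanism is visible in the vote algebra:
  when every node's acceptances are near-random, the complement encoding
  gives all classes nearly equal support ($1 - \lambda_q$ under unanimous
  rejection), so the fused argmax collapses onto a systematic guess, while
  individual sensors retain slightly more idiosyncratic signal. Fusion is a
  redundancy mechanism; it cannot recover information that no sensor still
  carries. Rotational disturbance, which preserves signal energy, does not
  trigger this collapse — fused curves dominate singles at every level and
  $S$ there.
* Weights are estimated once on clean data and frozen; no disturbed-sensor
  detection or adaptive re-weighting is attempted.
* The one-vs-rest decomposition scales linearly in $N$, but the node
  decision is only as good as its weakest base classifiers on
  hard-to-separate class pairs.
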