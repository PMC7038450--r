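---
title: "Methods: forehead pressure mechanomyography analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forehead pressure mechanomyography analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the problem

`pressmmg` analyses surface pressure mechanomyography (MMG) of the
forehead recorded with a textile pressure-mapping (TPM) headband: a
2 × 10 grid of fabric pressure sensors (1.5 cm pitch) sampled at a
nominal 15 ms interval with a 12-bit ADC, so every frame is a 2 × 10
grid of counts in [0, 4095]. Eyebrow actions (frontalis raising,
corrugator lowering — FACS action units AU1/AU2/AU4) change the
pressure distribution under the band; the package turns those changes
into features, classifies instructed facial expressions, and tests
whether spontaneous facial activity during a dual N-back
working-memory task correlates with the task's stimulus/input events
and with task performance.

Two experiment protocols are supported end to end:

1. **Instructed mimicking** — 300 stimulus trials per participant
   (5 repetitions of a 60-stimulus sequence: 32 basic eyebrow figures
   plus 28 emotional portraits, 4 actors × 7 emotions), each trial
   yielding one labelled analysis window.
2. **Dual N-back** — nine sessions per participant
   (2,2,2,3,3,3,2,2,2-back), 21–24 stimulus pairs per session every
   3 s, windows defined between consecutive stimuli.

## From frames to features

**Windows.** Mimicking windows run from the midpoint between the
'next' and 'record' clicks to 1 s after the two-second recording
countdown, so the neutral-to-expression transition is inside the
window. N-back windows are half-open onset-to-onset intervals
`[t_i, t_{i+1})`, so every frame belongs to exactly one window; the
tail after the final stimulus has no closing stimulus and is dropped.

**Key frames.** Each window's frame sequence `F(t)` is reduced to
eight 2 × 10 key frames: the per-pixel mean (KF1); the summed
successive differences (KF2, which telescopes to `F(last) − F(first)`);
the half-wave rectified sums of positive and of negative differences
(KF3, KF4, with `KF3 − KF4 = KF2` exactly — this identity is what
rules out reading the definitions as counts of signed steps); the
frames of maximal/minimal mean and maximal pixel standard deviation
(KF5–KF7, earliest frame on ties); and the mean of per-frame
thresholded grids in which pixels strictly below their frame's mean
are zeroed (KF8; pixels equal to the mean are kept, and the divisor is
the full frame count).

**Image moments.** Every key frame contributes the three second-order
central moments μ20, μ11, μ02 and Hu's seven moment invariants,
computed with x = column, y = row (0-based), giving the fixed 80-long
feature vector (`KF1..KF8 × [μ20, μ11, μ02, Hu1..Hu7]`). Numerical
conventions:

* If the total mass `|M00|` is below `ε = 1e-12 · max|I|` (floored at
  `1e-12`), the centroid is undefined and all ten outputs are 0. A
  single nonzero pixel likewise yields zeros (a point mass has no
  spread).
* Difference key frames can carry negative total mass. The normalized
  moments are defined as `η_pq = μ_pq / |μ00|^(1+(p+q)/2)`; the
  absolute value keeps the non-integer power real, preserves
  translation invariance, and guarantees the no-NaN/Inf contract.
  Signed intensities are otherwise used as-is, preserving
  direction-of-change information.

## Classification of mimicked expressions

Feature tables are assembled into three modes: eyebrow states
(Mode 1, with portrait-Neutral trials merged into the smaller basic
Neutral class, 1200/1200/1200), seven emotions (Mode 2, 400 each),
and eyebrow-based emotion groups (Mode 3: {Neutral, Joy, Sadness},
{Anger, Disgust}, {Fear, Surprise}, balanced to 800 each by seeded
uniform removal from the largest group). Evaluation is stratified
5-fold cross-validation pooled over participants; stratification is a
deliberate choice (plain folds risk empty classes at these class
counts). Classifier hyperparameters not fixed by the protocol are
exposed in `classifier_spec()`: KNN k = 5; cubic-polynomial SVM with
one-vs-one multiclass and unit cost; bagged trees with 200 (Mode 1) or
400 (Mode 2) learners; subspace-KNN with 30 learners on random
40-feature subspaces. Cross-mode transfer fits on Mode 1 and scores
Mode-3 rows through the emotion-to-eyebrow mapping, which partitions
the seven emotions exactly once.

## N-back scoring and condition statistics

The session score is `correct positive inputs / (positive stimuli +
false-positive inputs)`, pooled over the audio and position channels
(the dual task is scored as one task). Only window-opening stimuli
count: the final stimulus opens no response window. At most one input
per channel is honoured per window; duplicates warn and are ignored.

Each window carries four bits — stimulus positivity and input presence
per channel — from which eight Boolean conditions C1–C8 are derived
(any positive stimulus; any positive input; both inputs equal stimuli;
any positive correct input; any positive input or stimulus; the same
conjoined with both inputs matching; any channel-wise input/stimulus
match; any wrong positive input, i.e. red feedback). C5–C7 are
best-effort readings of tersely named conditions and are documented as
conventions in `label_window()`.

For every condition × feature, the z-scored per-window feature values
are split into condition/opposite groups and binned into 26 equal bins
over [−2, 2]; out-of-range values are clipped into the edge bins so
every window contributes. The pair is balanced (each histogram scaled
to half the total window count — shape-preserving) and compared with
the two-histogram chi-square statistic `Σ (a−b)²/(a+b)` over bins with
positive mass. Degrees of freedom are fixed at 25 (bins − 1)
regardless of skipped empty bins, matching the method's convention,
and the p-value is the analytic upper tail. The significance threshold
is 0.05 with no multiple-testing correction — a deliberate mirror of
the method being implemented, and a caveat for interpretation: at
α = 0.05 about 4 of 80 features are expected significant by chance.

Session-level prediction aggregates each session's windows into 320
features (mean, SD, range, excess kurtosis per feature; zero-variance
features have kurtosis defined as 0), labels sessions by
above/below-median score (the median, not the mean, following the
protocol's own summary statistic), and cross-validates subspace-KNN
for three pools: all participants and the least/most expressive
halves.

## The synthetic cohort

No participant recordings are distributed, so the package ships a
generator that emulates both protocols; it is first-class, tested
code, and every study in the examples and tests runs on it. What it
models, and what it deliberately does not:

* **Anatomy.** Per-participant resting contours (700–1500 counts plus
  smooth column structure and per-pixel jitter). Raising loads the
  upper sensor row broadly (frontalis-like); lowering loads the medial
  columns (corrugator-like). These spatial forms are modeling choices:
  no per-class pressure patterns are published for this device.
* **Emotions.** The seven emotion templates derive from the eyebrow
  archetypes per the grouping above, plus fixed cohort-wide
  perturbation patterns scaled by a `separability` knob. The true
  confusability of, say, Joy vs Neutral in pressure space is
  unknowable from desk data; the knob is explicit rather than a claim
  of realism.
* **Expressiveness.** Cohort expressiveness spans the uniform
  quantiles of [0, 1]. Instructed-mimicking amplitude keeps a floor
  (compliant participants express when asked; default 35% of the
  450-count peak). Spontaneous reactions during the N-back task scale
  differently: the probability of any visible reaction goes with
  expressiveness squared, so the bottom of the cohort keeps a nearly
  constant face for whole sessions — the phenotype actually observed
  in such studies — while reaction amplitude, when a reaction occurs,
  is roughly common (70–100% of peak).
* **Cognitive-load reactions.** Phasic reactions (asymmetric,
  lateralized mixtures of the two archetypes lasting 1–2.2 s) are
  injected into windows with red feedback (p = 0.9 × scale), missed
  positives (0.8 × scale) and positive events (0.1 × scale); a tonic
  corrugator-like tension proportional to the session's realized error
  rate models sustained mental effort. Lateralization matters for the
  feature set: a centred symmetric burst barely moves second-order
  central moments and Hu invariants (which normalize mass away), while
  an off-centre burst shifts the centroid and the moment trio
  strongly.
* **Behaviour.** Hit probabilities 0.50 (2-back) and 0.20 (3-back)
  plus a per-participant skill offset (±0.10) and a 0.08
  false-positive rate give simulated median session scores near 0.33
  and the expected score drop in the 3-back block.
* **Nuisance.** Per-pixel Gaussian noise (SD 8 counts), integer
  quantization, slow sinusoidal drift (12 counts, ~90 s period), and a
  continuous per-session placement shift (N(0, 0.35) columns, clamped
  to ±1, linear interpolation) emulating headband re-seating at a
  fraction of the sensor pitch.

Not modelled: skin/muscle biomechanics, sensor hysteresis and creep,
motion artifacts correlated across sessions, inter-channel crosstalk,
and any audio/visual stimulus content. Consequently, passing tests
show that the *pipeline* recovers structure that the generator puts
in under realistic noise; they do not certify accuracy figures on
real recordings, whose inter-subject variability is far richer.

## Problem sizes and determinism

The shipped studies use the protocol scale throughout: 20
participants × 300 trials (6000 windows) for the mimicking experiment
and 20 × 9 sessions (~3900 windows) for the N-back experiment; unit
tests use smaller synthetic fixtures built in code. All randomness is
seed-threaded (`make_cohort()`, the per-session simulators, fold
assignment, Mode-3 balancing, subspace sampling), and every
`with_seed`-wrapped computation restores the caller's RNG state, so
identical seeds give byte-identical results.

Known limitations worth restating: the session-level expressive-pool
advantage is a modest effect at this cohort size (180 sessions) and
single-seed evaluations carry ±0.05 accuracy noise; the chi-square
scan inherits the method's lack of multiplicity control; and the
feature ordering (hence "feature 48") is a convention of this
implementation — key-frame-major, moment-minor — that need not match
any other implementation's numbering.
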