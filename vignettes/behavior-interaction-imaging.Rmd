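---
title: "Behavior and interaction imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior and interaction imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadimaging)
```

## What the package computes

`dyadimaging` quantifies early mother–infant interaction along two
modalities and uses the resulting features to classify developmental
outcome groups.

On the **vision side**, the position of a colored wristband on the infant's
hand is followed through a frame sequence by a bootstrap particle filter
and summarized, over a one-minute analysis window at 25 frames/s (1500
coordinate pairs), into 21 descriptors of explored space, movement
dynamics, motionless episodes, and trajectory curvature.

On the **audio side**, a timeline of labeled vocal segments is merged into
speech turns, and 16 features describe each partner's vocal activity, the
dyadic silence and overlap structure, the infant's responsiveness to the
mother within a 3-s window, and the split of mother speech into motherese
(infant-directed speech) versus other speech, produced by a two-stream
Gaussian-mixture classifier.

The two feature families feed a deliberately simple classifier — a
one-feature threshold rule (decision stump) on PCA-reduced features under
leave-one-out cross-validation — which is appropriate for cohorts of a few
dozen dyads, and a point-biserial correlation ranking that identifies which
raw features carry the group contrast.

All stages are exercisable end to end on synthetic dyads with known
generating parameters; no clinical recordings are needed to validate the
machinery.

## Speech turns and synchrony

A *speech turn* is a maximal same-speaker vocal stream containing no
internal silence of 150 ms or more: segments of the same speaker and
category separated by strictly less than `turn_gap_ms` (default 150 ms) are
merged. A gap is only treated as silence if no other segment of the same
speaker lies in it — a noise burst between two vocalizations interrupts the
stream rather than bridging it. Categories (vocalization, mother noise,
atypical infant vocalization) never merge across each other. All intervals
are half-open `[onset, offset)` integer milliseconds, so abutting segments
neither overlap nor leave gaps, and each speaker's occupancy, pause and
(for the mother) noise ratios sum to one by construction.

Dyadic features follow directly: *silences* are joint vocal gaps strictly
longer than 150 ms; the *overlap ratio* is the fraction of the interaction
during which both partners vocalize. The *infant synchrony ratio* counts a
mother vocalization as answered when an infant vocalization **onset** falls
in the window `(offset, offset + 3 s]` after the mother's **offset**.
Design choices here, made where the turn-taking literature leaves room:

* The window is anchored at the mother's offset, and onsets already inside
  the mother's turn (overlap) do not count — this avoids double-counting
  overlap as responsiveness.
* Each mother vocalization is counted at most once, and an onset lying in
  two overlapping windows answers only the earlier one. Attribution is
  computed against all mother vocalizations before restricting to the
  motherese / non-motherese subsets, which keeps the overall ratio a
  count-weighted mean of the subset ratios.
* Atypical infant vocalizations count toward vocal occupancy but not as
  synchrony responses (configurable via `count_atypical_as_response`).

## Hand tracking

The tracker is a bootstrap particle filter with a first-order
(constant-velocity) motion model: prediction adds Gaussian noise to both
position and velocity, which lets the filter absorb the abrupt changes of
direction and speed that infant hand movements show. Occlusion is part of
the state: each particle carries a visibility boolean that flips with
probability 0.05 per frame; occluded-flagged particles receive a constant
observation likelihood instead of an image likelihood. The observation
model is the Bhattacharyya similarity between the color histogram of a
small patch (5×5 px, 4 quantization levels per RGB channel) and a kernel
color model of the wristband, computed once per frame as a similarity map
via per-bin box filters. Resampling is systematic (lower variance than
multinomial) and triggered only when the effective sample size falls below
half the particle count. The per-frame estimate averages the
visible-flagged particles; a frame is emitted as missing when the weighted
visible fraction or the best patch similarity falls below
`likelihood_floor`. Tracking is combined with detection: when the filter
has lost the target but the frame contains a strong color response, half
the particles are re-seeded there, which makes re-acquisition after
occlusion reliable.

Trajectories from different recordings are made comparable by a
per-recording scale factor from a reference object of known size
(`normalize_trajectory`). Only 2D trajectories are supported: with
realistic amounts of missing data, 3D reconstruction from two views is not
robust, and 2D descriptors carry the clinically relevant signal.

## Movement descriptors

The 21-descriptor vector covers four families, all computed over visible
frames only and never differentiated across an invisibility gap:

* **Space**: coordinate ranges and SDs, and the exact farthest-pair
  distance (verified against a quadratic scan in the tests).
* **Dynamics**: speed and acceleration magnitude from central finite
  differences of coordinates smoothed by a 5-frame (200 ms) centered moving
  average, with one-sided differences at run ends; mean, SD and max of
  each, plus path length and the count of supra-threshold movement units.
* **Pauses**: maximal runs with speed strictly below a threshold for at
  least 4 s. The threshold defaults to 2% of the trajectory's own maximum
  smoothed speed — a scale-free choice that survives zoom differences — and
  can be fixed absolutely via `pause_speed_absolute`.
* **Curvature**: the plane-curve formula
  $\kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^{3/2}$ on smoothed coordinates,
  excluding samples slower than the pause threshold (curvature is
  numerically meaningless near zero speed) and samples whose smoothing
  window was truncated at a run edge (the asymmetric average there distorts
  the second derivative). On a sampled circle of radius $R$ the estimate is
  within 2% of $1/R$.

Any descriptor that cannot be computed (too few visible frames) is `NA`
and propagates to the classifier's imputation step rather than silently
becoming zero.

## Motherese detection

Mother vocalizations are classified motherese vs other speech by fusing two
streams: a *segmental* stream (13 mel-frequency cepstral coefficients per
25 ms/10 ms frame, 12-component diagonal-covariance GMM per class) and a
*suprasegmental* stream (per-segment prosodic vector — F0 mean/SD/range/
slope by autocorrelation with parabolic refinement, energy statistics,
voiced fraction, duration — 15-component GMM per class). Each stream's
score is a log-likelihood ratio; per-frame segmental log-likelihoods are
averaged, not summed, so segment duration does not dominate the fusion.
The fused score is $\lambda s_{seg} + (1-\lambda) s_{supra}$ with
$\lambda = 0.4$ weighting the segmental stream (the weighting convention is
exposed in `fusion_lambda`), and the decision threshold is 0 (equal
priors). EM uses k-means initialization, a variance floor of $10^{-6}$
(small training sets), and stops at a relative log-likelihood change of
$10^{-6}$; the log-likelihood trace is non-decreasing by construction and
is cross-checked against an independent EM implementation in the tests.

Agreement between classifier and ground truth is measured by ICC(2,1) —
two-way random effects, absolute agreement, single rater — with the
F-distribution confidence interval. Absolute agreement is the right form
here because a classifier that systematically shifts labels should be
penalized; the implementation reproduces an independent reference to nine
decimals on a fixed table.

## Outcome classification

Features are mean-imputed and z-scored with training-fold statistics, PCA
is fit on the standardized training fold keeping the smallest component
set with ≥95% explained variance (deterministic sign convention), and a
decision stump — exhaustive search over features, threshold midpoints and
both polarities, with fully specified tie-breaking (lower feature index,
lower threshold, "greater" polarity) — is trained on the components.
Everything is refit inside every leave-one-out fold, so no statistic of
the held-out dyad leaks into its own prediction; `pca_outside_loo = TRUE`
provides the laxer protocol in which the PCA is fit once on all dyads, a
variant worth having because small-cohort studies are often ambiguous on
this point. The stump classifies in PCA space by default while the
correlation ranking always works on raw features, whose names are
interpretable; `classify_on = "raw"` switches the stump to raw features.
Missing features are imputed by default; `missing_policy =
"drop_incomplete"` reproduces the alternative of discarding incomplete
dyads.

## The synthetic dyad generator

The generator is first-class, tested code; its defaults define the
conditions under which the pipeline is validated.

**Timelines** are renewal processes (exponential inter-onset gaps at a
given events/minute rate, exponential durations) for each partner, with
synchrony planted explicitly: after each mother vocalization the infant
responds with probability `p_sync`, the response onset uniform in the 3-s
window after the mother's *final* (truncated, rounded) offset — so
`p_sync` is exactly the quantity the synchrony ratio estimates, and the
estimator is unbiased within Monte-Carlo error. Category and motherese
labels are realized by independent coin flips; planted responses are
always plain vocalizations.

**Trajectories** are persistent-velocity random walks in the unit box with
reflection at the borders, velocity redrawn with per-frame probability
`turn_abruptness`. Pause episodes and occlusion gaps are Poisson-count
episodes placed uniformly in the free space so every episode fits whole;
pause durations are floored at 4.5 s with an exponential tail (mean
`pause_dur_mean_s`), so every planted pause exceeds the 4-s detection
minimum and the planted per-minute rate is directly recoverable — an
unshifted exponential with mean 6 s would leave ~49% of pauses
undetectable and make "recovery" ill-defined.

**Videos** render the trajectory as a yellow disk (radius 3 px) on a noisy
gray 64×64 background, with no disk on occluded frames.

**Cohorts** mirror a three-group design (19 controls, 22 + 10 at-risk
dyads split by outcome). The default group effects follow the directions
reported for at-risk infants — fewer infant vocalizations, lower synchrony,
lower velocity/acceleration variability, more motionless time — with
magnitudes deliberately in the strong-signal regime so that the full
pipeline reaches ≥90% leave-one-out accuracy at a 51-dyad cohort. These
magnitudes are package defaults for validation, not estimates of real
effect sizes, and real recordings differ in ways the generator does not
model: no camera jitter, lighting or skin-color confusion on the vision
side; no acoustic noise, overlapping speech in one channel, or
annotator disagreement on the audio side. Passing tests therefore
demonstrate the correctness of the machinery, not clinical performance.

**Synthetic voices** contrast a high, strongly modulated F0 (280–400 Hz
with 60–140 Hz excursions) against a low, flat contour (170–220 Hz) over a
five-harmonic source — the prosodic caricature the detector relies on, not
intelligible speech.

## Problem sizes and numerical choices

The validation suite uses 51-dyad cohorts (180-s timelines, 60-s
trajectories), 100-replicate recovery runs, 100-vs-100 voice corpora at
8 kHz, and two 24-s tracking videos at 20–30% occlusion; these sizes give
stable Monte-Carlo estimates while keeping a full run in well under a
minute per stage. Noteworthy numerical conventions: integer milliseconds
for all annotation arithmetic (no float drift), frames for trajectories,
conversion only through `fps`; strict inequalities exactly as stated in
the turn ("< 150 ms") and silence ("> 150 ms") definitions; a tiny
positive floor on the pause threshold so that an entirely motionless
trajectory still registers one full-length pause; and mixture variances
floored at $10^{-6}$.

## Known limitations

* The EAF reader covers only a small subset of ELAN's format (aligned
  annotations, tier id = speaker, value = category).
* Raw-audio diarization is out of scope: timelines come from annotations
  (human or synthetic), and the motherese detector consumes in-memory
  waveforms rather than audio containers.
* The tracker is tuned for a saturated color blob on a dull background;
  real footage with skin-tone confusion or lighting drift would need a
  richer observation model.
* With 10 outcome-positive dyads in the default cohort, the WS+ vs WS−
  contrast is intrinsically noisy; the package reports it but the
  headline validation target is the stronger group-vs-control contrast.
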