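# dyadimaging

Behavior and interaction imaging for mother–infant dyads: an R toolkit for
quantifying early dyadic interaction from multimodal recordings and using
the resulting features to classify developmental outcome groups. It is
aimed at researchers in developmental psychology and computational
psychiatry who study interactional synchrony, infant motor behavior and
infant-directed speech in at-risk cohorts (e.g. infants with early
epileptic encephalopathies followed for autism / intellectual-disability
outcomes), and who need every analysis stage to be testable without
clinical data.

## What it computes

**Vision.** A bootstrap particle filter tracks a colored wristband through
video frames with a first-order motion model (prediction–observation–
estimation), a per-particle visibility boolean for occlusion, patch
color-histogram Bhattacharyya likelihoods, and systematic resampling.
The resulting 2D trajectory (1500 coordinate pairs for one minute at
25 fps, missing frames marked) is normalized by a fixed scene reference
and summarized into 21 hand-movement (HM) descriptors: explored space
(ranges, SDs, farthest pair), dynamics (velocity and acceleration
statistics, path length, movement units), pauses (speed below threshold
for ≥ 4 s), and plane-curve curvature

    κ = |x′y″ − y′x″| / (x′² + y′²)^{3/2}.

**Audio.** Vocal annotations are merged into speech turns (same-speaker
segments separated by < 150 ms of silence) and summarized into 16
speech-turn-taking (STT) features: per-partner vocalization / noise /
pause occupancies, dyadic silences (> 150 ms), overlap ratio, and the
infant synchrony ratio — the fraction of mother vocalizations answered by
an infant vocalization onset within 3 s of the mother's offset — plus
motherese-split ratios from a two-stream GMM classifier (13 MFCCs with a
12-component mixture; prosodic F0/energy/duration vector with a
15-component mixture; score fusion λ·s_seg + (1−λ)·s_supra, λ = 0.4),
validated by ICC(2,1) against ground truth.

**Classification.** Features are imputed/standardized and PCA-reduced
(≥ 95% variance) inside every leave-one-out fold, classified by an
exhaustively-searched decision stump, and ranked by point-biserial
correlation with the class. Accuracy is reported as a percentage of a 2×2
confusion matrix (e.g. 12 errors among 51 dyads → 76.47%).

**Synthetic dyads.** A tested generator produces vocalization timelines
with controllable response probability `p_sync`, trajectories with planted
pause/occlusion episodes, blob videos, and motherese-vs-flat voice
corpora, with group effects mirroring the directions reported for at-risk
infants — so parameter recovery and end-to-end discrimination are
verifiable against ground truth.

## Worked example

```r
library(dyadimaging)

cohort   <- make_cohort(cohort_spec(seed = 42))     # 19 TD / 22 WS- / 10 WS+
features <- cohort_features(cohort)                 # 51 x (16 STT + 21 HM)
out      <- classify_cohort(features, mode = "ws_vs_td")
out$result
#> Leave-one-out classification: accuracy 100.00% (n = 51)
#>    TD WS
#> TD 19  0
#> WS  0 32
head(out$correlations[, c("feature", "modality", "r", "p")], 5)
#>         feature modality          r            p
#> 1    hm_accMean    video -0.9402844 1.403172e-24
#> 2      hm_accSd    video -0.9231491 5.553968e-22
#> 3     hm_velMax    video -0.9146818 6.510322e-21
#> 4 hm_pathLength    video -0.9110138 1.748787e-20
#> 5    hm_velMean    video -0.9050122 8.062413e-20
```

The confusion matrix counts true groups in rows and predictions in
columns: at the default (strong-signal) generator effects every dyad is
classified correctly under leave-one-out. The correlation table ranks raw
features by the absolute point-biserial correlation with the group label;
here the at-risk group's lower movement vigor dominates, with negative
signs because the at-risk group is coded as the higher class level. The
same call with `mode = "wsplus_vs_wsminus"` contrasts the two at-risk
subgroups, where infant vocalization and synchrony features rise to the
top of the ranking.

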