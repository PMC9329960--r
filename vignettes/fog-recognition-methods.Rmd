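---
title: "Video-based freezing-of-gait recognition: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Video-based freezing-of-gait recognition: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fogvision)
```

This vignette documents the science and the engineering decisions inside
`fogvision`: what each stage of the pipeline assumes, which parameters matter
and why they have the defaults they have, what the synthetic cohort does and
does not emulate, and where the design was genuinely open.

## Problem setting

Freezing of gait (FOG) is an episodic arrest of locomotion in Parkinson's
disease, typically in the intermediate and advanced stages, often with a
6–8 Hz trembling of both legs, lasting from about a second to tens of
seconds. The input to this package is not video but its skeletal reduction: a
per-frame estimate of 25 body keypoints (the BODY_25 layout: nose, neck,
shoulders, elbows, wrists, hips, knees, ankles, eyes, ears, toes, heels) with
per-keypoint confidences, produced by a monocular pose estimator at nominally
30 frames/s during a timed-up-and-go walk (walk out, turn, walk back; a
narrow-corridor variant provokes FOG more readily). Ground truth is
frame-based: turn intervals, FOG intervals, and *unknown* intervals for spans
where even expert annotators cannot decide (e.g. a voluntary rest stop).
Frame intervals are 0-based and half-open `[start, end)` throughout, which
removes off-by-one ambiguity at boundaries.

## Scale normalization

A monocular camera confounds body kinematics with apparent size: a subject
walking toward the lens grows by tens of percent across a clip. Each frame is
therefore normalized independently:

1. minimum axis-aligned rectangle over keypoints with positive confidence;
2. width and height expanded by `expand_frac = 0.30`, symmetric about the
   rectangle center;
3. translation so the expanded rectangle's upper-left corner is the origin;
4. multiplication by `s = target_height / expanded height`, `target_height = 80`.

The normalized expanded rectangle has height 80 exactly in every frame, and
the transform is invariant to any positive isotropic scaling and translation
of the input (tested to 1e-9 and exactly). Two choices here were open:
*which* rectangle height defines `s` (we use the expanded rectangle — the
same one that defines the origin), and whether to normalize per frame or per
clip. We normalize per frame, because the stated motivation is the
near/far apparent-size change *within* a recording; per-clip normalization
would leave exactly that trend in place.

## The signal bank

From normalized positions the package derives, per frame: speeds and
accelerations of all 25 keypoints in x and y (forward first difference
multiplied by fps; the last sample is replicated so all channels keep the
frame count), the interior knee angles (angle at the knee between the
knee→hip and knee→ankle vectors, 0–180°), and the absolute left–right
x-distances of 8 keypoint pairs (hips, knees, ankles, big toes, shoulders,
elbows, wrists, ears). The pair distances are the turn detectors: seen from
the front, the shoulder-to-shoulder (etc.) x-separation collapses toward 0
mid-turn and re-expands.

Differentiation scheme and pre-filtering were open choices. We use plain
forward differences and **no** low-pass filter by default: human movement
lives below ~15 Hz and a 30-Hz sampling rate already cannot represent
anything above that, so at this frame rate a 15-Hz filter is nearly a no-op;
an optional zero-phase 4th-order Butterworth low-pass (`lowpass_hz`) is
available for noisier pose streams. Pairwise distances use the x-axis only —
that is the axis on which turning is visible frontally.

Pose estimators drop keypoints (occlusion, blur). `interpolate_low_confidence()`
repairs any keypoint-frame with confidence below `conf_min = 0.1` by linear
temporal interpolation between the nearest confident frames (nearest-value
fill at the edges), sets the repaired confidence to `conf_min` (making the
repair idempotent), and reports the repaired fraction.

## Windows and features

Signals are cut into 2-s windows stepped by 0.1 s (`n = 60` samples at
30 fps; window count `floor((T - 2)/0.1) + 1`). A window is labeled `turn`
when more than half its frames are inside a turn interval; its FOG label is
`unknown` if it touches any unknown frame, `fog` if at least half its frames
are FOG, else `nonfog`. Unknown windows are excluded from training *and*
scoring — their truth is undefined by construction.

Time-domain statistics follow their printed formulas even where those differ
from textbook conventions: the *kurtosis coefficient* is the non-central
fourth moment `mean(x^4)`; the *90th percentile* is the order statistic at
position `1 + 0.9(n-1)` with linear interpolation; *signal entropy* is the
Shannon entropy of a 10-bin histogram of the window (a Shannon-type formula,
not SampEn — conventional sample entropy is available separately as
`sample_entropy()` and via the `sampen` statistic); the *clearance factor*
uses its conventional definition `max(|x|) / (mean sqrt(|x|))^2`, with the
crest-factor-identical variant available behind `clearance_literal = TRUE`
because some published feature tables typeset the two identically; *min of
squared samples* is taken literally as `min(x^2)`.

The spectrum estimator is the minimal one consistent with "the Fourier
transform of the window": a rectangular-window periodogram of the
mean-removed samples, one-sided, scaled so that `sum(power) * df` equals the
window variance (Parseval-consistent; verified against a direct-summation
DFT oracle at 1e-9). Band powers integrate the power density by the
trapezoid rule with linear interpolation at the band edges, which makes
adjacent bands exactly additive. The *average frequency* is implemented as
the power-weighted mean frequency — the printed `sum(F.T.(x))/n` is ambiguous
for complex coefficients, and the power-weighted mean is the standard
"center frequency" estimator. The 3.5–15 Hz band is exactly representable at
30 fps (Nyquist = 15 Hz); wider requests clip with a warning. The freezing
index is `band(3–8) / band(0.5–3)`, capped at 1e6 when locomotor power
vanishes (an empty window must not produce infinities).

## Models

Three XGBoost binary classifiers: **motion** (walk vs turn; trained on all
labeled windows, FOG windows included — freezing can occur in either stage
and the stage router must see it), **Walk-FOG** (walking-stage windows) and
**Turn-FOG** (turning-stage windows). Each FOG model is trained after:

* **transition removal** — training windows whose start lies within 0.5 s of
  any FOG/non-FOG boundary are dropped (their 2-s content genuinely mixes
  both regimes); test windows are never filtered;
* **SMOTE** — the minority class (FOG) is oversampled to parity by convex
  interpolation between minority nearest neighbors (`k = 5`, reduced with a
  warning for tiny minorities); synthetic rows inherit the subject of their
  base row so grouped cross-validation stays subject-pure;
* **gain-ranked forward selection** — features ranked by total split gain of
  a single fit at the grid-center hyperparameters; prefixes grown in gain
  order and scored by subject-grouped cross-validated GM; the best prefix
  wins, ties to the smaller one; caps default to 50/20/12 features for
  motion/walk/turn;
* **grid search** — each grid point scored by the same subject-grouped GM;
  the default grid is deliberately small (learning rate 0.1, 50 trees, depth
  {3, 5}, column subsample {0.8, 1}); the larger 108-point grid is available
  as `fog_grid("full")` when compute allows.

When a stage has no usable FOG training windows, its model degrades to a
constant non-FOG predictor with a warning — a fold simply cannot learn what
it has never seen. When no inner fold carries both classes (tiny turn-FOG
training sets), forward selection falls back to the gain ranking up to the
cap and the final fit uses the grid center, again with warnings.

At inference the motion model routes each window to the FOG model of its
*predicted* stage (during training, routing uses the annotated stage); the
FOG decision threshold on the probability is 0.5.

## Episodes, postprocessing, and metrics

Maximal runs of equally-labeled windows merge into episodes spanning from the
first window's start to the last window's end. Predicted FOG episodes
shorter than a minimum duration are relabeled non-FOG and merged; the
threshold is the 10% linear-interpolation quantile of the annotated FOG
durations **of the training subjects of the fold** — computing it over all
marked durations would leak the held-out subject's labels. With only a
handful of training episodes this quantile is noisy, and a fold whose
training episodes are all long will delete true detections of short
episodes; that is the documented price of the false-positive filter, and the
package accepts it rather than peeking at test durations.

Episode scoring: a truth FOG episode counts as detected when at least one
predicted-FOG window's span overlaps it; a truth non-FOG episode counts as
correct when it contains no predicted-FOG window, where *contains* means the
window's full 2-s span lies inside the episode. Containment (rather than
overlap, or a window-center rule) is deliberate: every correctly detected
FOG boundary produces windows that straddle the boundary and genuinely
contain freezing; charging those against the flanking non-FOG episode would
structurally destroy specificity for any detector operating on 2-s windows,
while genuine mid-episode false alarms are still counted in full. The
episode metrics are checked against an independent frame-rasterizing oracle
in the tests. Window metrics are standard confusion-matrix rates plus a
midrank (tie-aware) rank-statistic AUC; GM = sqrt(sensitivity × specificity)
everywhere, and the identity GM² = sens × spec is asserted to 1e-12.

Evaluation is leave-one-subject-out: feature selection, SMOTE, grid search
and the duration threshold see training subjects only (each fold records a
fingerprint of its training rows, and the tests verify the held-out subject
never appears). Pooled (micro) metrics over the union of held-out
windows/episodes are the headline numbers; per-fold metrics are kept
alongside. AUC is reported for the motion model, whose scores are pooled
across folds. Because windowed features are autocorrelated within a subject,
between-group feature tests first average the feature per subject and group
and then apply a paired Wilcoxon signed-rank test across subjects
(`paired_subject_wilcoxon()`; at least 5 complete pairs, degenerate all-zero
differences report p = 1 with a flag).

`run_loso_experiment()` runs the full simulate → extract → LOSO chain for
both the staged pipeline and a non-staged single FOG model on identical
folds and writes the side-by-side comparison — the staged-vs-flat contrast
is part of the method's claim and is built in. The package is driven from R
(functions + this vignette + `scripts/acceptance.R`); no shell CLI is
provided.

## The synthetic cohort

`simulate_cohort()` generates what the pipeline assumes about real
recordings, and nothing more:

* **walking** — antiphase limb oscillation at a per-subject cadence drawn
  from 0.8–1.2 Hz (inside the 0.5–3 Hz locomotor band), foot lift at the
  same frequency, and forward progression rendered as a smooth apparent-scale
  change over 0.7–1.3× (the raw bounding-box height varies by more than 20%
  across a clip while normalized walk amplitudes stay stationary — this is
  exactly what the rectangle normalization must remove). Foot x-swing is
  0.45× the gait amplitude so ankle/toe left–right distances stay positive
  during straight walking and collapse only in turns;
* **turning** — all x-offsets from the body midline scaled by |cos(πu)| as
  the turn progresses, collapsing the 8 pair distances to near 0 and
  re-expanding them; progression pauses;
* **FOG** — locomotor oscillation damped to 5%, 6–8 Hz tremor added to the
  lower-limb keypoints (3–5 template pixels), progression arrested; a frozen
  turn holds the turn phase in place;
* **degradation** — Gaussian keypoint jitter (0.5 px) and confidence
  dropouts (1% of keypoint-frames).

Defaults mirror the clinical study conditions: 12 subjects, FOG prevalence
0.26 (ceiling → 4 affected subjects), episode durations uniform on 1–15 s,
1–4 episodes per affected subject with each episode falling in the turning
stage with probability 0.25 (the clinical cohort had 8 of 33 episodes in
turns). Recordings are walk (18–22 s) → turn (2.5–4 s) → walk, extended by
the inserted FOG time. Annotations are exact by construction. The end-to-end
recovery evaluation in the tests and the acceptance script uses 2–4 episodes
per affected subject — the stated recovery condition — because with single
episodes a lone turn-stage episode can belong to one subject only and is
then unlearnable under LOSO by the constant-predictor rule above.

What the simulator does **not** emulate: real pose-estimator error structure
(correlated misdetections, left/right swaps), FOG phenotypes (trembling vs
akinetic), festination, camera motion, multi-person scenes, or perspective
foreshortening beyond isotropic scale. Passing the synthetic recovery test
therefore demonstrates that the pipeline's machinery — normalization,
features, staged models, episode logic, LOSO bookkeeping — recovers the
signatures it is built around; it does not certify clinical performance.

## Problem sizes and numerical conventions

The test suite and acceptance script run the full LOSO experiment on the
12-subject cohort (≈5,900 windows, 480 features) with feature caps 12/8/6
and the small default grid — sizes chosen so a complete run stays in the
minutes range on a single core while every pipeline stage is exercised at
its real shape. Fixed numerical conventions: quantiles use linear
interpolation (type 7); degenerate statistics return defined values
(skewness 0 at zero variance, crest/clearance 0 at zero denominators,
freezing index capped at 1e6); grid and selection ties break
deterministically (first grid row, smallest prefix); training rows are
canonically ordered before fitting so results are invariant to input row
order; all stochastic steps (simulation, SMOTE, tree fitting) are governed
by explicit seeds and re-runs are bit-identical.

## Known limitations

* Episode-level rates on a 12-subject synthetic cohort have coarse
  granularity (1/12 per FOG episode); they indicate recovery, not precision.
* The per-fold 10% duration quantile is unstable with few training episodes;
  folds without short training episodes will miss short test episodes.
* A stage with no FOG training windows cannot detect FOG in that stage
  (constant predictor by design).
* The motion model assumes the frontal-view geometry of the TUG protocol;
  oblique camera angles would weaken the pair-distance turn signatures.
* Knee angles from 2D projections are not anatomical joint angles; they are
  used only as relative bending signals.
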