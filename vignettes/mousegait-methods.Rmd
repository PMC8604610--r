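---
title: "Methods: footfall detection and gait estimation in mousegait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footfall detection and gait estimation in mousegait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousegait)
```

## The measurement principle

A mouse runs left to right along a glass trackway lit by green LEDs along
the glass edges and red LEDs above. The green light is trapped in the glass
by total internal reflection except where a paw presses on it, so a camera
below sees bright green footfall blobs on a dark red-tinted background.
Every quantity this package produces derives from those blobs: where they
are (centroids), how big and bright they are (area, intensity), and when
they appear and disappear (the contact timeline).

The package assumes: a fixed camera at a known frame rate (default 60 fps);
locomotion in one known direction (a config flag mirrors the rules for
right-to-left runs — direction reversals mid-run are not detected and will
be misclassified); and lighting strong enough that paw pixels clear the
green threshold while the background stays well below it.

## Detection

Detection composes four primitives, each exposed on its own:

1. `threshold_green()` keeps pixels with G ≥ τ inside the analysis band.
   The comparison is inclusive so the default τ = 205 is boundary-stable.
2. `proximity_cluster()` forms single-linkage clusters: connected
   components of the graph linking pixel pairs at Euclidean distance ≤ d.
   Single linkage is deliberate — a paw print is a palm blob plus detached
   toe digits, and transitive chaining is what joins them. With integer
   coordinates the components are found over a precomputed offset
   neighbourhood (every integer offset of norm ≤ d); non-integer input
   falls back to pairwise distances. Both routes are checked in the test
   suite against an independent brute-force transitive-closure oracle.
3. `filter_cluster_size()` keeps clusters with N ∈ [N_min, N_max],
   inclusive on both ends. Sub-minimum clusters are dust and specks;
   super-maximum ones are tail drags, body or nose-slide streaks.
4. `compute_centroid()` takes the arithmetic mean of member coordinates.

Defaults (τ = 205, d = 2 px, N ∈ [65, 510]) are the ROC-optimal operating
point for 1080×1920 trackway video; all four are config-exposed because
they scale with resolution and lighting.

Coordinates are 0-based with x = column (along the trackway) and
y = row (across it), origin top-left. The G channel is used as decoded;
no colour-space conversion.

## Classification

Frames with exactly four clusters anchor the labeling: larger-x pair →
front paws; within each pair, smaller y → right paw (the camera views the
glass from below). Exact coordinate ties — measure-zero on real data — are
broken by the other coordinate, then by cluster size descending, so the
result is deterministic.

Labels then propagate to a fixpoint: an unlabeled cluster within
`propagation_distance` (default 20 px) of a labeled cluster at most
`frame_window` (default 1) frames away takes that label. Candidates are
processed nearest-first (ties: earlier source frame, then stable
coordinate keys), and an assignment that would give a frame two clusters
with the same label is skipped — so the nearer candidate wins and the
invariant "one cluster per (frame, label)" holds by construction. Because
labels are only ever added, the iteration terminates in at most one pass
per cluster. Propagation is symmetric in time (both previous and
successive frames), which makes the outcome independent of the order in
which detections arrive; a permutation-invariance test enforces this.

Whatever remains unlabeled — nose or tail touches of valid cluster size,
isolated noise — is marked `Unclassified`, kept in the output for
diagnostics, and excluded from gait computation.

The 20 px / 1 frame defaults suit native resolution at 60 fps: during
stance a centroid moves only by detection jitter (≪ 20 px/frame), while
consecutive distinct footfalls of different paws are a body length apart.

## Gait parameters

Steps are maximal runs of contact frames per paw, bridging gaps of at most
`gap_tolerance` (default 2) missing frames, since an isolated missed
detection would otherwise split one contact phase into two spurious steps.
For step *j* with first/last contact frames t_f, t_l:

* stance Rⱼ = (t_l − t_f)/fps, and swing Dⱼ = (t_f of step *j*+1 − t_l of
  step *j*)/fps — both written so durations are nonnegative;
* the step's reference frame t_m is ⌊(t_f + t_l)/2⌋ snapped to the nearest
  frame actually detected (earlier on ties), and stride length is the
  Euclidean distance between consecutive steps' t_m centroids;
* duty cycle = ΣR/(ΣR + ΣD); with a single step no swing is observed and
  the duty cycle is 1 by convention;
* averages of per-pair quantities (stride, swing) divide by the number of
  values present, S − 1 for S steps — dividing by S would bias them
  downward by construction;
* cadence is reported per paw (that paw's S over the run duration) and
  pooled (all-paw S over the run duration), since "steps per second" is
  used in both senses in practice.

Run duration is (last − first frame with any detected paw)/fps. Paw
supports count frames by how many paws are in contact (a paw is in contact
throughout each step interval, gap-bridged): diagonal dual counts frames
where either diagonal pair (LF+RR or RF+LR) is down, three- and four-point
use at-least-k semantics, which gives the checkable nesting
four_point ≤ three_point. Supports are reported both as seconds
(shared frames / fps) and as fractions of run duration. Note the fraction
can exceed 1: contact-frame counts are inclusive of both endpoints while
run duration is a frame difference.

Paw area is the green-pixel count of a cluster and intensity its mean G
value; per-paw averages are means over that paw's clusters (a two-level
mean for intensity). Lengths are in pixels; an optional `px_per_mm` scale
adds millimetre columns. Base of support (a lateral-distance parameter) is
not computed: it needs a body-axis estimate the footfall centroids alone
do not provide.

## Evaluation

`match_detections()` matches predictions to truth boxes per frame, greedily
by centroid-to-box-center distance, one-to-one; a prediction qualifies if
its centroid falls inside the box or within `max_match_dist` (default
20 px) of its center. A correct-label match is a hit; a mislabeled match
consumes the box and counts as a false (misclassification is a false, not
a miss — the box was found, the identity was wrong); unmatched boxes are
misses and unmatched predictions falses. H:M:F percentages use
hits+misses+falses as denominator, so they sum to 100 before rounding.

The ROC analysis (`roc_sweep()`) treats the detector as a binary classifier
over the trackway band. One threshold is swept with the others fixed; at
each value TP/FP/FN are counted as events of one 20×20-px cell each and
TN is the remaining cell count, ⌊region area/400⌋ cells per frame (301 for
the native 1720×70 band) minus the event cells — counting all four outcomes
in the same cell unit keeps TPR = TP/(TP+FN) and FPR = FP/(FP+TN)
commensurate. Matching here is label-agnostic, since the sweep evaluates
detection, which precedes classification. The empirical curve is the
straight-line interpolation of the (FPR, TPR) points; `roc_auc()` is its
trapezoidal area after anchoring (0,0) and (1,1), and
`optimal_threshold()` maximizes Youden's J = TPR − FPR (ties: smaller FPR,
then smaller threshold). `roc_random_control()` provides a chance-level
reference whose expected AUC is 0.5.

## The synthetic generator

`generate_run()` renders what the optics produce, not what a mouse looks
like: a red-tinted background with mild sub-threshold green texture
(uniform ±10 around G = 40), paw blobs as a palm disk plus a fan of four
digit disks — disjoint from the palm but within 2 px of it, so clustering
must chain them — with per-pixel G drawn uniformly from [paw_G − 10,
paw_G], and optional distractors: bright specks of 4–9 px (below N_min),
a 3-row tail streak of > 510 px (above N_max), and a palm-sized "nose
touch" far ahead of the paw tracks (a valid-size distractor that must end
up Unclassified). The nose blob's brightness is separately configurable,
which is how the separable ROC test set (paws at G ≈ 230, distractor at
G ≈ 180) is built.

The gait is a trot: diagonal pairs share a phase, the two pairs offset by
half a stance+swing cycle. When the duty factor drops below 0.5 a strict
half-cycle trot has aerial phases and *no* four-paw frames — and the
classifier, like the real protocol, needs at least one four-support frame
to anchor labels — so the default offset is min(⌊cycle/2⌋, stance − 2),
keeping at least two four-support frames per cycle, as real mice
approaching a walk do. During stance a paw is fixed in world coordinates;
each stance advances by the configured stride. Every rendered blob gets a
truth box, and `analytic_parameters()` returns the closed-form
expectations: run duration and step count exactly from the schedule,
stride exactly, stance/swing/duty cycle as the idealized ratios
stance/fps, swing/fps, stance/cycle, and supports by enumerating the
contact table.

What the generator does not emulate: fur and body silhouette, partial or
crescent-shaped contacts, pressure-dependent blob growth during a stance,
motion blur, lighting gradients, or direction reversals. Passing tests
therefore demonstrate the algorithmic correctness of the pipeline under
the stated optical model, not robustness to every artifact of live-animal
video.

Two discretization facts matter when comparing recovered to analytic
values. A stance of k frames spans (k−1)/fps seconds, so recovered stance
and swing sit within one frame of the idealized k/fps. And the duty-cycle
ratio pools S stances against S−1 swings, so its error is O(1/S); the
recovery checks therefore use runs of five strides per paw, where the
combined error stays within one frame per cycle (1/cycle in duty-cycle
units). These are properties of the estimators, not of the generator.

## Numerical and design choices

* All threshold comparisons are inclusive; the printed defaults are
  boundary values and must not flip with a < vs ≤ choice.
* Warps (radial undistortion, rotation) use inverse mapping with bilinear
  interpolation and constant-black fill; output size depends only on the
  config. Sines/cosines within 1e-12 of 0 or ±1 are snapped exact so
  quarter-turn rotations are lossless. The distortion model is
  single-coefficient radial about the image center, with the radius
  normalized by the half-diagonal; one coefficient is adequate for the
  short action-camera lenses these rigs use, and k1 = 0 bypasses the
  sampler entirely (bit-exact identity). A forward-warp counterpart
  (Newton inversion of the radial polynomial) exists to build test scenes
  with known distortion.
* The interactive calibration such rigs normally do in a GUI is replaced
  by `calibrate_preview()` (writes before/after images for a parameter
  choice) plus the YAML config; nothing in the algorithmic path is
  interactive.
* Degenerate inputs are contracts, not crashes: empty pixel sets cluster
  to an empty list; a frame with no four-cluster anchor warns and yields
  all-Unclassified; zero classified footfalls is an error for
  `summarize_gait()`; zero events is an error for `hmf_score()`; an ROC
  point with TP+FN = 0 carries NA TPR and is dropped from AUC.
* The pipeline consumes no randomness — only the generator does, under an
  explicit seed which it restores afterwards — so reruns are
  byte-identical.
* Outputs are CSV and JSON rather than binary workspace formats.

## Problem sizes

The shipped tests and the acceptance script run entirely on reduced-canvas
synthetic runs (100×400 px, 60–190 frames each): detection closure on 20
two-stride runs, parameter recovery on 10 five-stride configurations with
duty cycles 0.40–0.80, the clustering oracle on 100 random point sets of
up to 50 points, and 200 chance-level ROC replicates. These sizes exercise
every code path while keeping the whole suite in the low minutes on one
core; the full-resolution geometry is available via
`synthetic_gait_config(full_canvas = TRUE)` and changes nothing but scale.

## Known limitations

* Merged footfalls (two paws touching within the linking distance) become
  one cluster; no watershed splitting is attempted.
* Turning or reversing mice violate the direction assumption and will be
  misclassified — visible downstream as inflated false rates.
* Sub-pixel blob localization is not attempted; centroids inherit
  half-pixel quantization from thresholding.
* Supports depend on the gap-bridged step intervals; pathological
  detection dropouts longer than `gap_tolerance` shorten them.
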