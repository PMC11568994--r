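---
title: "Multi-positive contrastive descriptors for retinal image registration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-positive contrastive descriptors for retinal image registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusreg)
```

`fundusreg` implements a feature-based registration pipeline for color
fundus photographs built around domain-specific keypoints — blood vessel
crossovers and bifurcations — and dense per-pixel descriptors trained with
multi-positive, multi-negative contrastive objectives.  This vignette
explains the models, the parameters that matter, the synthetic data the
package tests itself on, and the numerical and design choices that were
genuinely open.

## The registration pipeline

Given a *fixed* and a *moving* image, registration proceeds in four stages:

1. **Detection.** A fully convolutional encoder–decoder (U-Net style)
   regresses three heatmap planes at input resolution: crossover
   confidence, bifurcation confidence, and a combined plane containing all
   keypoints.  Discrete keypoints are the strict local maxima of the
   combined plane within a `window` × `window` neighbourhood (default 7 px)
   that reach an intensity `threshold` (default 0.35); each detection takes
   the class whose plane responds more strongly at that pixel.
2. **Description.** A dilation-based fully convolutional network (modified
   L2-Net contract: no spatial downsampling, one descriptor per input
   pixel) yields a dense H×W×D field, L2-normalized per pixel, and each
   keypoint reads the descriptor of its nearest pixel.
3. **Matching.** Cosine similarity (a dot product, since descriptors are
   unit-norm) with *bidirectional* nearest-neighbour filtering, computed
   independently per class: crossovers only match crossovers, bifurcations
   only bifurcations.
4. **Transform estimation.** A projective transform (homography) is
   estimated from the matches with RANSAC over 4-point minimal samples
   solved by the normalized direct linear transform (DLT), then refit by
   least squares on the consensus set.

## Heatmap regression targets

Binary keypoint ground truth is converted into Gaussian confidence
surfaces: a unit-height isotropic Gaussian of standard deviation `sigma` is
placed at every keypoint, and overlapping Gaussians are composed with the
pointwise **maximum**, not the sum.  The choice matters: targets are
detection confidences, so a peak amplitude of exactly 1 at every keypoint
keeps the extraction threshold meaningful regardless of local keypoint
density.  Gaussians are truncated at radius 7σ, below double-precision
relevance for the tolerances used in the tests.  `sigma` defaults to 5 px
at the generator resolution and is configurable; the desk-scale protocols
in this package use σ = 3 px, which separates neighbouring keypoints
(minimum spacing 6 px) sharply at the 256² scale and localizes detections
to within a pixel or two — the property match precision at 3 px rewards.

Whether inference-time extraction should run on the combined plane or on
the two class planes separately is not dictated by the model; this package
extracts on the combined plane and classifies by comparing the two class
planes at the detected pixel, with exact ties resolved to bifurcation so
extraction is deterministic.

## The multiviewed batch

Descriptor training uses one base image plus N augmented views (default
N = 9).  Views are related to the base by sampled affine transforms —
rotation ±60°, per-axis translation up to 0.25 × image size, isotropic
scale in [0.75, 1.25], shear ±30° — followed by photometric augmentation:
an HSV jitter applied always, and additive Gaussian pixel noise of
standard deviation 0.05 applied with probability 0.25.  Keypoints are
detected **once, on the base image only**, and carried through each view's
affine transform, so every keypoint identity has known coordinates in all
N + 1 views.

With K surviving keypoints the batch holds K(1+N) samples; each anchor has
N positives (the same keypoint in the other views) and (K−1)(N+1)
negatives — every other keypoint everywhere, including the anchor's own
view.  A keypoint whose warped position leaves any view (with a 3 px
border margin, so nearest-pixel descriptor sampling stays valid) is
dropped from *all* views.  The alternative — masking it only in the views
it leaves — would make K ragged across views and break the index structure
of the loss sums; uniform dropping keeps the combinatorics exact at the
cost of slightly fewer anchors per batch.

## The contrastive objectives

Descriptors are L2-normalized, so cosine similarity is the dot product,
and every similarity is divided by a temperature τ (default 0.1).  Writing
z_ik for the descriptor of keypoint k in view i:

**Supervised contrastive (SupCon) loss.**  For every *ordered* pair of
views (i, j), i ≠ j, and every keypoint k, the anchor z_ik is pulled
towards z_jk against a denominator that sums the anchor's similarities to
every other sample in the batch (its own view excluding itself, and every
other view in full).  The total is scaled by 1/N — exactly the printed
normalization, with no additional 1/K; the optimizer's learning rate
absorbs the overall scale.  Because the inner log-ratio does not depend on
j, the ordered-pair sum effectively repeats each anchor's term N times,
which the 1/N prefactor cancels; the implementation follows the formula
literally rather than "simplifying" it.

**Multi-positive InfoNCE (MP-InfoNCE).**  For every *unordered* view pair
(i, j), j > i, the anchor is z_ik and the denominator is restricted to the
pair: the anchor's own view (excluding itself) plus all of view j.  The
sum is normalized by C(N+1, 2) · K.  For N = 1 each per-anchor log-ratio
term coincides exactly with the corresponding SupCon term — the test suite
asserts this identity — but the two scalars differ by their
normalizations, so no scalar equality is enforced.  One subtlety worth
stating: because the anchor is always the lower-indexed view of the pair
and the denominator is anchor-specific, MP-InfoNCE is *not* invariant to
permuting views; this follows from the formula as printed and is covered
by an explicit counterexample in the tests.

**Triplet baseline.**  `max(0, margin − s_ap + s_an)` on cosine
similarities with margin 0.05, one positive (the same keypoint in another
view, chosen uniformly) and one uniformly random non-matching keypoint as
the negative.  The negative-selection rule is not part of the triplet
formulation itself; uniform sampling is the simplest baseline consistent
with single-positive single-negative training, and is the package's
choice.

Both multi-positive losses are evaluated with max-subtraction inside each
log-ratio, so τ as low as 0.01 cannot overflow.

## Network training

*Detector.*  MSE over the three planes jointly, Adam, single-image
batches.  The learning rate starts at 1e-4 and is multiplied by 0.1
whenever the validation loss (25% of the scenes are held out) fails to
improve for 2500 batches; training stops when the rate falls below 1e-7.
A `max_steps` cap exists for desk-scale runs; the rate-floor rule remains
the default stopping criterion.  Spatial augmentation (rotation ±90°,
scale [0.9, 1.1], shear ±20°) warps image and target heatmaps with the
same transform; HSV jitter (±0.02 hue, ±0.15 saturation/value — magnitudes
are the package's defaults, configurable) touches only the image.

*Descriptor.*  Adam at a constant 1e-4 (triplet: 1e-5), temperature 0.1.
One "epoch" is one optimizer step on one multiviewed batch built from one
base image, matching the single-image-batch usage throughout.  Training
evaluates the network only on receptive-field patches centred at the
(rounded) keypoint coordinates of each view — mathematically identical to
dense evaluation followed by sampling, since the network is fully
convolutional, but an order of magnitude cheaper, which is what makes CPU
training practical.  Sub-pixel keypoint coordinates are resolved by
rounding half up per axis; descriptors are selected, never interpolated,
because interpolating unit vectors would break the unit-norm contract.

The convolutional engine itself (im2col + GEMM convolutions with analytic
backward passes, 2×2 max-pooling/upsampling, Adam) is part of the package,
in compiled code; training is deterministic given the seed, and the
backward passes are verified against central finite differences in the
test suite.

## RANSAC and its parameters

Minimal 4-point samples are solved by DLT with Hartley normalization
(centroid at the origin, mean distance √2) — unstated in most
presentations but standard for conditioning.  The consensus rule uses the
**one-way** reprojection error (fixed points mapped into the moving frame)
with an inlier threshold of 5 px; a symmetric error would double the cost
and complicate the documented inlier semantics for no benefit at these
scales.  Randomized mode draws up to 10,000 samples with early stopping at
99.9% confidence; exhaustive mode evaluates all C(M, 4) samples and is
used wherever the evaluation protocol calls for the full budget.
Samples with any three (near-)collinear points are skipped.  Ties between
hypotheses with equal inlier counts are broken by the smaller mean inlier
error, then by sample order, so estimation is deterministic given the RNG
stream.

## Evaluation metrics

*Registration score.*  A pair is successful at threshold t if its mean
control-point error is ≤ t.  The success ratio is swept over the integer
grid t = 1…25 px and the AUC is the mean of the 25 ratios.  The grid
discretization and the closure of the success rule (≤ rather than <) are
conventions fixed by this package and used consistently; they may differ
from other implementations by small constants.  Failed registrations enter
with error +∞ so they penalize every threshold rather than disappearing.

*Category aggregation.*  Per-category AUCs (categories S: high overlap,
P: low overlap, A: high overlap with vessel alteration), their unweighted
mean, and a weighted mean using per-category pair counts as weights.

*VTKRS.*  The variable-top-keypoint registration score recomputes the
registration score while only the top-n best-matched keypoints per class
(ranked by descriptor similarity) enter exhaustive RANSAC, for n = 3…25; a
class with fewer than n matches contributes all it has.  The VTKRS AUC is
the unweighted mean of the per-n AUCs — the curve's AUC under the same
mean convention as above.  When n exhausts every available match the per-n
score equals the unlimited registration score exactly, which the tests
assert.

## The synthetic generator

Real fundus datasets with keypoint or control-point ground truth cannot be
bundled, so the package generates its own study material: a bright,
lightly textured circular disc (coarse low-frequency noise plus a
vignette) carrying dark vessel trees of tapering cubic Bézier segments.
Each tree undergoes a fixed number of branch events — every event endpoint
is a ground-truth *bifurcation* — and crossings between different trees
are ground-truth *crossovers*.  Keypoints closer than 6 px are merged
(matching the detector's local-maxima window, so ground truth remains
recoverable) and points within 6 px of the disc edge are dropped.  All
geometry is deterministic given the seed.

Registration fixtures warp a scene by a sampled projective transform
(affine plus small perspective terms), then corrupt the moving image
photometrically: a multiplicative illumination halo, a mild Gaussian
defocus blur, and a global HSV shift.  Ten control points are sampled on
vessel centrelines inside the overlap; their moving coordinates are the
exact images of the fixed ones, so fixture error is zero by construction.
Category S uses mild transforms (rotation ±12°, translation ≤ 0.06 × size),
category P uses large translations (≤ 0.30 × size) so overlap drops, and
category A uses the S geometry but additionally erases a random subset of
vessel segments in the moving image, emulating keypoints vanishing under
pathology progression.  These ranges are the package's one-time choice of
"realistic" for 256² fundus-like images: S/A pairs overlap ≳ 0.9, P pairs
≈ 0.55–0.75, and the category ordering of overlaps is property-tested.

What the generator does *not* emulate: optic disc and macula, vessel
calibre/colour variation between arteries and veins, camera noise
statistics, or true pathology appearance.  Passing tests on this material
demonstrates that the pipeline's machinery — detection, invariant
description, matching, robust estimation, scoring — works end to end; it
does not certify performance on clinical images.

## Desk-scale protocols and problem sizes

The package's self-contained experiments (test suite and the acceptance
script) run on one CPU in minutes, with sizes chosen once:

- 12 scenes of 256², 4 vessel trees × 8 branch events (≈ 50–70 ground-truth
  keypoints per scene); 10 scenes train, 2 are held out.  The density is
  chosen so a detector finds roughly 40–55 keypoints per image, the regime
  this class of methods operates in: with far fewer keypoints, the chance
  level of mutual matching (one over the per-class candidate count) rises
  to the point where even an untrained descriptor looks acceptable, and
  the trained/untrained comparison loses its meaning.
- Heatmap σ = 3 px at this scale: sharper target peaks localize detections
  to 1–2 px, which matters because match precision is scored at 3 px.
- Detector: 3 resolution levels, base width 8, trained on random 128²
  crops for up to 2,000 steps at learning rate 1e-3 (the plateau schedule
  needs far longer horizons than desk scale; a constant-rate short run
  with the same machinery is the package's desk-scale choice — the
  full-scale defaults remain 1e-4 with the 2500-batch patience).
- Descriptor: D = 32, widths (16, 16, 32, 64), dilations (1, 2, 4, 8)
  (receptive field 31 px), N = 9 views, MP-InfoNCE, learning rate 6e-4,
  ≤ 1,500 steps, at most 24 keypoints per batch.  The full-scale defaults
  (D = 128, constant 1e-4, 15,000 steps) are configuration away but take
  hours on CPU.  The training-time patch evaluation runs in single
  precision; inference and all loss arithmetic stay double.

Held-out match quality is measured as *mutual-match precision*: the
fraction of bidirectional matches that land within 3 px of the known true
warp, on held-out scenes warped with the descriptor-training augmentation
distribution (rotations up to ±60°).  This is the distribution the
descriptor is supposed to be invariant over, and it separates trained from
untrained networks sharply; an untrained network's random projections
still correlate nearby patches, so milder evaluation warps would flatter
it.

## Known limitations

- The synthetic material is geometrically faithful but photometrically
  simple; absolute scores do not transfer to DRIVE/FIRE-scale imagery.
- Networks are desk-scale by default in the tests; the printed full-scale
  configurations are supported but not exercised end to end.
- The AUC discretizations (threshold grid, VTKRS mean over n) are fixed
  package conventions; compare numbers across implementations only after
  checking conventions.
- Matching is O(K_fixed × K_moving) per class with dense similarity
  matrices; fine for hundreds of keypoints, not designed for tens of
  thousands.
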