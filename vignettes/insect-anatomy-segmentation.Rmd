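---
title: "Segmenting insect anatomy: model, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting insect anatomy: model, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`insectseg` detects, classifies and pixel-extracts the four anatomical
components of a mosquito-like insect — thorax, abdomen, wings and legs —
from RGB images, using an anchor-based instance segmentation network
trained entirely on CPU. This vignette explains the model, the losses, the
synthetic data the package trains and tests on, and the numerical and
design choices a user or reviewer may want to audit.

## The problem and the model

Each image contains one insect on a roughly flat, textured surface. The
goal is instance segmentation: for every anatomical component, a class
label, a tight bounding box and a binary pixel mask. Legs are the hard
case: a leg is a 1–3 px wide stroke, so inside any rectangle around a leg
the background pixels outnumber the leg pixels by one to two orders of
magnitude, and a pixel-level learner biased toward the majority class will
happily call every pixel background.

The pipeline is the standard two-stage anchor-based design:

1. **Backbone + feature pyramid.** A small residual CNN (a stride-4 stem
   followed by `backbone_depth` residual stages, default 2) produces
   feature maps at strides 4/8/16. A top-down pathway with lateral 1×1
   connections merges them into a pyramid with a uniform channel count
   (default 16), so each object is detected at a scale-appropriate level.
   The depth and widths are configuration points: the defaults are sized
   for 128 px inputs and CPU training, not for photographic detail.
2. **Region proposals.** Anchors are tiled at every grid cell of every
   pyramid level (3 sub-scales × 5 aspect ratios per cell; ratios 1/3–3
   cover bent-leg bounding boxes). A shared head scores each anchor
   foreground/background (2-way softmax) and regresses box deltas.
   Decoded boxes are clipped, lightly suppressed (IoU 0.8) and a generous
   top 192 kept: at desk scale the proposal stage ranks imperfectly, and
   the 5-way head classifier — not the proposal cap — is the precision
   filter, so starving it of candidates only loses recall.
3. **Three parallel heads on RoI-aligned patches.** Each proposal is
   bilinearly RoI-aligned (no coordinate quantization; 2×2 samples per
   bin) to a 7×7 patch for a 5-class classifier (4 anatomy classes +
   background) and a class-agnostic box-delta regressor ("tightening"),
   and to a 28×28 patch for the mask head.

All forward and backward passes are implemented in the package (R with
Rcpp/RcppArmadillo kernels for convolution, RoIAlign and resampling);
there is no deep-learning framework underneath. Gradients are
hand-chained and verified against finite differences in the test suite.

### The mask head sees the image as well as the features

A stride-4 feature cell is 4 px wide; a 1 px leg stroke is invisible at
that resolution no matter how the head upsamples. The mask head therefore
works at the mask resolution (28×28) directly, on the RoI-aligned pyramid
features *concatenated with the RoI-aligned raw image* (3 extra
channels). The features carry semantics ("this box is a leg"), the image
channels carry pixel-level edges. This is the package's own design choice
for the desk-scale configuration; with a deep high-resolution backbone the
extra channels would be redundant.

### Box coding

Boxes are continuous, half-open, top-left-anchored `(x, y, w, h)`. The
regression targets are the usual normalized offsets

$$t_x = (x^* - x_a)/w_a,\quad t_y = (y^* - y_a)/h_a,\quad
  t_w = \log(w^*/w_a),\quad t_h = \log(h^*/h_a),$$

with natural logarithms; encoding and decoding are exact inverses, which
the tests check to 1e-9.

## Losses

* **Classification** (proposal objectness and the 5-way head):
  categorical cross-entropy, $-\log p$ of the true class.
* **Masking**: per-pixel binary focal loss
  $-(1-p_t)^{\gamma}\log p_t$ with $\gamma = 2$, where $p_t$ is the
  predicted probability of the pixel's true class. The modulating factor
  down-weights well-classified (overwhelmingly background) pixels so the
  rare leg pixels keep a share of the gradient. Setting $\gamma = 0$
  recovers plain binary cross-entropy, available as
  `train_config(mask_loss = "bce")` for the comparison below.
* **Box tightening**: smooth-L1 on each of the four delta residuals
  ($0.5x^2$ below $|x|=1$, $|x|-0.5$ above), summed over components and
  averaged over positive RoIs.

Probabilities are clamped at 1e-7 before any logarithm. Each branch is
reduced by the mean over its contributing elements, and the total loss is
their unweighted sum, so the branch weights are scale-free.

### What the focal-vs-BCE comparison shows — and what it does not

At the loss level the imbalance mechanism is directly measurable: on a
100:1 background:foreground pixel set with a fixed miscalibrated
predictor, the share of gradient magnitude attributable to foreground
pixels is several-fold larger under the focal loss than under BCE (a unit
test computes both shares). At the training level the package provides
`compare_mask_losses()`, which trains the same small mask network twice —
focal vs BCE — at identical budget, initialization and data order on leg
crops from a thin-leg synthetic dataset, and reports leg-pixel recall and
precision of each arm.

On this generator's data the directional claim — strictly higher leg
recall under focal at matched budget — does **not** hold: the two arms are
statistically indistinguishable, with BCE often marginally ahead. The
reason is instructive. The synthetic legs, however thin, are separable
from the background by local contrast, so foreground and background
learning are cooperative: the same dark-stroke feature that classifies a
leg pixel correctly also classifies background correctly, and the
majority-class gradient never opposes minority-class learning. Focal's
down-weighting then acts mostly as a smaller effective learning rate.
The regime where focal wins requires foreground pixels that *compete*
with easy background for model capacity — true of real smartphone imagery
of mosquitoes, not of these renderings. The test suite nevertheless
asserts the directional claim, and that one assertion is expected to
fail; we keep it failing rather than weaken it, because the comparison
itself (matched budgets, seeds, reported precision) is the deliverable.

## Training

Optimization follows the published recipe: SGD, momentum 0.9, weight decay
0.001, and a four-phase learning-rate schedule (1e-3, 5e-4, 1e-5, 1e-6)
whose breakpoints sit at epoch fractions 0.2/0.4/0.8, so shorter runs
keep the schedule's shape. Two desk-scale adaptations, both configurable:

* `lr_scale` (default 20) multiplies the schedule. The printed rates were
  tuned for 1024 px inputs and a deep pretrained backbone; the tiny
  randomly initialized network needs proportionally larger steps.
* `batch_size` default 2; the gradient of a batch is averaged. For very
  small datasets (overfit experiments) `batch_size = 1` converges faster.

Per image and step, the proposal stage is trained with a *dense,
class-balanced* objectness loss: every anchor contributes, positives and
negatives each carrying half the total weight. We initially used the
conventional 64-anchor random sample, but with the tiny backbone the
sampled loss never separated foreground from background scores — adjacent
stride-4 anchors share nearly identical features, and the sparse sample is
dominated by that ambiguity. The dense balanced form is deterministic,
costs almost nothing at this scale, and separates cleanly. The delta
regression term still uses positive anchors only.

The heads are trained on ground-truth-anchored RoIs: each instance
contributes its exact box, a mildly jittered copy (scale 0.9–1.15, shift
±10%), and a strongly jittered copy (scale 0.7–1.4, shift ±25%) labeled
positive when its IoU with the instance still reaches 0.4 — so the
classifier and regressor see mid-quality boxes the way they will at
inference — plus up to 8 random background boxes (IoU < 0.3). The mask
branch is choosier: it trains only on boxes with IoU ≥ 0.55 (the exact
and mildly jittered copies, and the better strong jitters). Mask targets
from sloppy boxes blur the thin-leg masks, while at inference the mask is
computed on the *tightened* box, which is near-ground-truth whenever the
regressor has done its job. Mask targets are the instance mask
RoI-aligned to the box at 28×28 and thresholded at 0.5.

Augmentation follows the source recipe: left-right flips (probability
0.5; polygon x-coordinates mirrored) and Gaussian blur with σ drawn from
[0, 1.2] (pixels only). Instance counts and labels are never changed.
Training is fully deterministic given the seed, including augmentation
draws; two runs produce identical loss logs.

At inference, proposals are classified and tightened, per-class NMS is
applied, and the mask is predicted *on the final box*, upsampled
bilinearly into the box footprint and thresholded at 0.5. Predicting the
mask on the final box rather than the proposal matters: the mask and the
box must share a coordinate frame.

## The synthetic generator

`generate_insect()` renders a stylized insect with exact ground truth:
one thorax (dark filled ellipse), one abdomen (elongated ellipse
adjoining the thorax along the body axis, sometimes with pale transverse
bands), 1–2 semi-transparent wings (alpha 0.4, overlapping the abdomen,
as wing extractions overlap the body in real specimens), and 3–6
two-jointed legs of width 1–3 px fanning out from the thorax. Both leg
bends curl in the same rotational sense so each leg arcs — keeping its
bounding-box aspect moderate — and neighbouring legs stay roughly
parallel rather than crossing. The background is a low-frequency
intensity gradient plus Gaussian noise plus dark speckle grains
(dust/debris), so foreground is not separable by a global threshold.
Every instance is annotated with the exact polygon or polyline used to
render it; annotation/render consistency is exact by construction.

What the generator reproduces from the real task: the class-count shape
(1 thorax : 1 abdomen : ~1.5 wings : ~4.5 legs per image), inter-class
mask overlap (wings over abdomen), and above all the background-vs-leg
pixel imbalance (leg pixels are <2% of a 256 px image at 1 px width, and
>80% of every leg bounding box is background). What it does not
reproduce: photographic texture, specular detail, scale variation from
camera geometry, occlusion between specimens, or leg pixels that resemble
the substrate. Passing tests on this data demonstrate that the pipeline's
machinery is correct and trainable, not that the trained weights transfer
to photographs.

Determinism: a fixed `seed` gives byte-identical pixels and annotations;
dataset generation derives per-image seeds from the master seed, and
nothing disturbs the caller's RNG state.

## Evaluation

Detections are matched to ground truth greedily in score order, each
ground truth used at most once; a detection is a true positive if its IoU
with its best unmatched ground truth reaches the threshold (0.30 / 0.50 /
0.70 are reported). IoU is computed on masks by default — the end goal is
pixel extraction — with box IoU as an option. Precision and recall are
micro-averaged over images; undefined ratios are reported as
not-applicable, never silently as 0 or 1. Average precision integrates
the precision-recall curve with 101-point interpolation (the maximum
precision at any recall at or above each grid point), and mAP is the
arithmetic mean over the four classes. A supplementary pixel-level
precision/recall table is available because instance-level and
pixel-level readings of leg accuracy can differ sharply. All of this is
cross-checked in the tests against brute-force rank-cutoff oracles on
small random detection sets.

## Problem sizes and numerical choices

The suite exercises the pipeline at deliberate desk scale: 128 px images,
a 2-stage backbone (~60k parameters), single-image overfit runs of a few
hundred epochs, an end-to-end run with 16 training and 6 validation
images at 60 epochs, and a 200-image thin-leg dataset for the mask-loss
comparison. These sizes are the package's chosen study conditions for a
CPU workflow; the architecture scales by configuration (deeper backbone,
larger images, more proposals), not by code changes.

Other numerical choices: He-uniform initialization seeded from the
config (no pretrained weights, no downloads); anchor matching thresholds
0.7/0.3 with the argmax anchor of each ground truth forced positive;
gradient clipping at global norm 10; probability floor 1e-7; decoded
boxes clipped with a warning if `exp(t_w)` explodes; degenerate
(zero-area) polygons rasterize via their stroke, and an empty union in
IoU is an error rather than a silent zero.

## Known limitations

* The desk-scale model generalizes modestly: held-out mask mAP@0.50 on
  synthetic scenes is far below the ceiling a full-scale training run
  achieves, and wings (semi-transparent, low contrast) are the weakest
  class after legs.
* The focal-loss advantage over BCE does not manifest on this generator
  (see above); the package reports both arms rather than presuming the
  direction.
* Masks are predicted per detection box at 28×28 and upsampled, so mask
  boundary fidelity is limited by box size, as in any RoI-based design.
* Training is single-device and synchronous; there is no warmup, mixed
  precision, or multi-GPU path.
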