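---
title: "Methods: a lightweight star-operation detector for peanut leaf disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight star-operation detector for peanut leaf disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stardetect)
```

## The problem

Peanut foliar diseases (leaf spot, rust, nutrient deficiency) are recognised
in the field from photographs of leaves against cluttered soil and foliage
backgrounds. A detector for this task must localise small lesioned leaves in
640 x 640 images, distinguish six visually similar categories, and stay small
enough to run on embedded field equipment. `stardetect` implements a
lightweight anchor-free one-stage detector family for this setting, together
with the dataset protocol (five-operator augmentation with exact five-fold
expansion, stratified 7:2:1 splitting) and COCO-style evaluation
(precision, recall, AP over IoU thresholds 0.50-0.95, repeated-run
mean +- sd summaries).

Because no public image accession accompanies this problem setting, the
package ships a synthetic leaf-scene generator as its data source; see
"What the synthetic scenes do and do not show" below.

## Architecture

All builds share one skeleton: a backbone emitting a stride-8/16/32 feature
pyramid, a fusion block on the deepest level, a PAN-style neck (two top-down
upsample-concat-fuse stages, two bottom-up downsample-concat-fuse stages),
and three decoupled heads predicting per-cell class logits and
centre-to-side distances. Three independent swaps define the family:

* **Backbone**: a plain convolutional backbone (stride-2 convolutions,
  channel-split bottleneck blocks early, an area-attention fusion block at
  the stride-16 stage) versus the **star-operation backbone** - four stages
  of blocks computing `dw7x7(x) * (W1x1 x + b) + x`. The element-wise
  product of a depthwise spatial branch and a pointwise channel branch
  yields implicit high-order feature interactions at a cost linear in
  width, which is why the star backbone carries far fewer parameters at
  equal depth. The stem and stage entries are stride-2 convolutions with
  batch norm and ReLU6 (ReLU selectable); the star blocks themselves follow
  the bare multiplicative form with no internal activation, so zeroing the
  pointwise branch makes each block an exact identity - a property the test
  suite asserts to machine precision. A global-average-pooled
  classification head is deliberately absent: detection consumes the stage
  features directly.

* **Neck upsampler**: nearest-neighbour versus the **dynamic upsampler**.
  The dynamic upsampler resamples the source map at learned positions: a
  base half-pixel bilinear grid, plus a static offset branch (linear
  projection, channel-to-space rearrangement, fixed 0.25 range factor) and
  a dynamic branch in which one linear projection gates another through
  `0.5 * sigmoid(.)`. Offsets live in source-pixel units and sampling is
  bilinear with border clamping, so zeroed offsets reproduce an exact
  bilinear resize and a constant field passes through unchanged - both are
  asserted against per-pixel oracles.

* **Fusion block family**: the baseline branch-concat-merge block (one 1x1
  reduction; two branches of two chained units; concat of the three paths;
  a merge convolution with a learnable per-branch scale) versus the
  **SCSA-augmented** variant, which embeds spatial-channel synergistic
  attention in every branch unit. At attention sites the unit is
  area-attention + SCSA + a single 1x1 convolution (replacing the two-layer
  MLP); at bottleneck sites SCSA sits between the opening 3x3 convolution
  and a closing convolution that becomes pointwise, since SCSA's axis-wise
  gate already supplies spatial mixing. Keeping the unit family and area
  partition of the site unchanged makes the swap's parameter/FLOP effect
  come from the channel-mixing exchange alone, not from attention being
  added or removed.

### SCSA details

The spatial pathway pools the map along each axis, runs multi-scale (3/5/7)
1-D depthwise convolutions on the two pooled sequences, group-normalises
each axis response, and combines the two axis logits additively under one
sigmoid. Replicate (edge) padding is used in these 1-D convolutions so that
a constant input yields exactly constant sequences; group normalisation then
zeroes them and the gate collapses to 0.5 everywhere - an exact invariant
in the tests. The channel pathway forms single-token query/key/value
descriptors (query: pooled group-normalised features; key/value: per-channel
scalings of the pooled, normalised descriptor), takes a row-stochastic
softmax attention map over channels without a temperature (one is
config-exposed), gates the attended vector with a sigmoid weight from a
kernel-9 1-D convolution along the channel axis, and broadcasts the result
over space. The module output is the sum of the two pathways.

Two formulation ambiguities were resolved as follows, both config-exposed:

* The printed spatial gate operates on a fully pooled 1x1 descriptor, which
  makes multi-scale 1-D convolution degenerate (every kernel sees one
  position). The default therefore pools per axis and forms the gate from
  the two axis sequences; the literal fully-pooled reading is available via
  `scsa_spec(pooled_1x1 = TRUE)`.
* In the dynamic-offset gate `0.5 sigma(. )`, the sigmoid is applied to the
  first linear projection and multiplies the second
  (`0.5 * sigmoid(lin2) * lin3`); which operand is gated is ambiguous in
  the formulation, and the chosen reading makes the gate a bounded range
  controller.

Similarly, the star block's merge is implemented as the product of the two
branch outputs (depthwise x pointwise); the printed form multiplies the
depthwise *kernel* by the pointwise output, which is not dimensionally
consistent.

## The tensor engine

No deep-learning runtime is available to R here, and the blocks above are
the package's subject matter, so `stardetect` carries its own reverse-mode
automatic differentiation engine on dense arrays (layout `(H, W, C, N)`,
column-major). Dense convolution is one BLAS matrix product per layer via
cached im2col index matrices; depthwise convolution is a shift-and-accumulate
sweep; area attention, channel attention and bilinear grid sampling are
fused ops with hand-derived backward passes (grid sampling differentiates
through both the source map and the sampling positions). Every op is
verified against central finite differences, and the composite blocks are
re-verified end to end. Batch norm uses batch statistics (biased variance)
in training and running statistics in eval mode; group norm is per sample
and channel group with epsilon 1e-5.

## Calibrated scale

The family is instantiated at one fixed "nano" calibration, chosen once so
that the printed complexity figures of all ablation builds land on their
one-decimal roundings, and never adjusted afterwards; `sda_arch()` returns
the table. Parameters are exact learnable-element counts. FLOPs follow the
2-FLOPs-per-MAC convention over convolution, linear and attention matrix
multiplies at 640 x 640, excluding normalisation and activations;
grid-sample interpolation arithmetic is likewise excluded, as interpolation
is not a conv/linear/matmul operation under that convention. Serialized
size assumes two bytes per weight (half precision).

Two structural choices fell out of the calibration and are worth stating
as design decisions. First, the convolutional baseline places its
swappable fusion block at the stride-8 stage: at high resolution the
channel-mixing exchange moves FLOPs strongly while barely moving
parameters, which is what lets the fusion-block swap shed computation
without shifting the baseline's parameter total. Second, per-site MLP
ratios and area partitions differ across sites (deep blocks use compact
channel mixing; the stride-8 sites use bottleneck-family units), which is
the freedom that lets one fixed table serve all eight on/off combinations
of the three swaps consistently.

```{r complexity}
complexity(baseline_spec())
complexity(yolo_sda_spec())
```

## Training protocol

The reference protocol (batch 4, 150 epochs, 640 x 640 input) is the
default of `train_config()`. The optimiser is SGD with momentum 0.9 and
cosine learning-rate decay; the loss is binary cross-entropy over all cells
and classes plus complete-IoU regression on assigned cells (weight 2).
Ground-truth boxes are assigned to the cell containing their centre, at a
level chosen by normalized box size (under 0.15 to stride 8, under 0.35 to
stride 16, else stride 32). Distribution-focal box regression was
considered and not adopted: direct distance regression keeps the
hand-built graph compact, and the package's complexity calibration anchors
the head layout, so nothing downstream depends on the discretised-box
parameterisation.

Desk-scale checks use reduced problem sizes chosen as the package's own
test scale: the overfitting property trains the full three-swap build on
eight 64 x 64 synthetic scenes and requires the loss to halve within 300
steps; the pipeline smoke test runs generate-augment-split-train-evaluate
end to end on a handful of scenes.

## What the synthetic scenes do and do not show

`generate_scene()` renders elliptical leaves with class-conditional
appearance - lesion spot density, size and colour differ per class, and
nutrient deficiency shows chlorotic yellowing - over a textured soil
background, and returns exact bounding boxes. This exercises every
mechanical property a detector pipeline needs (class-discriminable
appearance, cluttered background, multiple objects, reproducibility) and is
sufficient for oracle tests, overfitting and pipeline smoke checks. It does
not reproduce field imagery: no leaf occlusion geometry, no illumination
extremes, no intra-class lesion morphology variation, no camera noise
statistics. Passing tests therefore demonstrate the correctness of the
implementation, not field-level accuracy; accuracy figures from real
field datasets are out of reach here because no public accession exists.

## Dataset protocol notes

Expansion treats "five-fold" as original plus four augmented copies whose
operators are drawn without replacement from the five kinds (rotation,
Gaussian noise, salt-and-pepper, brightness, exposure), so per-class counts
scale exactly by the factor. Default operator parameters (sigma 10/255,
density 0.02, brightness within 25 %, gamma in 0.7-1.4) are package
choices, config-exposed. Rotation maps boxes to the axis-aligned hull of
rotated corners, clipped, dropping boxes whose area falls below 10 % of the
original. Splitting uses global largest-remainder totals with per-class
allocation, so a 7360-item set yields 5152/1472/736; published splits that
differ slightly from exact ratios cannot be reproduced exactly because the
underlying rounding rule is not stated anywhere.

The repeated-run summary (`run_statistics()`) reports the sample mean and
the n-1 standard deviation, formatted "xx.x ± y.y" in percent. For a fixed
trained model, `sda_evaluate(runs = k)` quantifies evaluation variability
over seeded bootstrap resamples of the image set; variability across
training seeds is obtained by repeating training.

## Known limitations

* Pure-R training is desk-scale only: minutes for toy scenes, not hours of
  full-resolution epochs.
* The evaluation operating point for precision/recall is the F1-maximising
  confidence, config-exposed, since no operating point is prescribed.
* The channel pathway of SCSA modulates a pooled descriptor; spatial detail
  flows only through the spatial pathway.
* Checkpoints are R serialisations; no cross-framework export.
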