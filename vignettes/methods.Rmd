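---
title: "Flowering-stage detection with a coordinate-attention RepVGG YOLOv5s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flowering-stage detection with a coordinate-attention RepVGG YOLOv5s}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Estimating flower yield in a greenhouse requires knowing not just where
the flowers are but which developmental stage each one is in: buds are
picked for long-distance shipping, open blooms for short-distance sale.
`cryolo` implements a single-stage, anchor-based detector for this
flowering-stage phenotyping task — localizing chrysanthemum
inflorescences in top-down RGB images and classifying each as *bud* or
*blooming* — together with the two architectural components that give
the detector its name:

* a **coordinate attention** block, which replaces 2-D global pooling
  with two 1-D poolings (along height and along width), so the channel
  attention it produces retains positional information — useful when
  flowers are partially hidden by foliage; and
* **RepVGG blocks** at the backbone's stride-2 down-sampling positions:
  at training time a 3×3 conv+BN, a 1×1 conv+BN and (at stride 1) a
  BN-only identity branch run in parallel; after training the whole
  block is collapsed by **structural reparameterization** into one 3×3
  convolution whose outputs are arithmetically identical.

Everything runs on a single CPU. Because no deep-learning framework is
assumed, the package carries its own numerical core: compiled
im2col/gemm convolutions and a small reverse-mode autodiff tape. This
is deliberate — the package's central claim is an *exact equivalence*
between the multi-branch training network and the fused inference
network, and owning the forward-pass arithmetic is what makes that
claim testable to double precision (observed deviations are below
1e-12; the test suite asserts 1e-10 per block and end to end).

## The model

The detector follows the familiar small-scale ("s") layout: a 3×3
stride-2 stem, four backbone stages of (stride-2 down-sampling
convolution, CSP bottleneck), SPPF at the end, a PAN neck, and a 1×1
head per scale emitting `3 * (5 + nc)` channels at strides 8/16/32.
`depth_multiple = 0.33` and `width_multiple = 0.50` reproduce the
standard 7.2M-parameter network; the test suite uses
`width_multiple = 0.125` for speed.

Two knobs place the contributed blocks:

* `repvgg_sites` (default `1:4`): which of the four down-sampling
  convolutions are multi-branch RepVGG blocks;
* `coordatt_sites` (default `c(3, 4)`): which CSP stages are followed
  by coordinate attention. The source description of the architecture
  is a figure, not a machine-readable table; placing one attention
  block after each of the last two stages (immediately before the
  neck taps the P4/P5 features) is this package's reading, and both
  knobs are configurable so the plain-YOLOv5s ablation baseline
  (`integer(0)` for both) is always recoverable.

Choices the architecture description leaves open, and what this package
does:

* the squeeze nonlinearity in coordinate attention is stated only as "a
  non-linear activation"; we use SiLU for consistency with the rest of
  the network (configurable);
* the reduction ratio `r` is never given; we default to 32 (the
  original coordinate-attention convention) with a floor of 8 squeezed
  channels, both configurable. The squeeze convolution is followed by
  BN before the nonlinearity, as in the original design, although the
  equation as printed shows only the convolution — `squeeze_bn = FALSE`
  turns it off;
* RepVGG's original post-activation is ReLU; this network is otherwise
  SiLU throughout, so SiLU is the default (configurable);
* BN uses `eps = 1e-3`, momentum 0.03 (the YOLOv5 convention);
* the stem is a 3×3 stride-2 convolution, keeping every kernel in
  {1, 3} so the reparameterization story covers the whole backbone.

## Structural reparameterization

Folding BN into a preceding convolution uses the per-channel update

```
W'_i = gamma_i / sqrt(sigma2_i + eps) * W_i
b'_i = beta_i - mu_i * gamma_i / sqrt(sigma2_i + eps)
```

with the same `eps` the BN layer used (dropping it, as presentations
sometimes do "for simplicity", breaks exactness). The 1×1 branch is
lifted to 3×3 by zero-bordering; the identity branch becomes a 3×3
one-hot kernel (with per-group bookkeeping); parallel branches then
merge by summing kernels and biases, which is exact by linearity of
convolution. Stride-2 blocks have two branches (the identity is
impossible there), stride-1 blocks three; both merges are implemented
and tested. `reparameterize_model()` additionally folds every remaining
conv+BN pair, is idempotent, and always reduces the parameter count
(the test suite checks all three properties).

Equivalence is asserted against eval-mode BN (running statistics),
which is the mode in which the fused network is used. All arithmetic is
double precision; per-block and whole-model deviations are required to
stay below 1e-10, far inside the 1e-4 tolerance that would be needed in
single precision.

## Loss and training

The loss is the YOLOv5-style composite the field uses when the source
is silent: CIoU box regression on assigned anchors, binary
cross-entropy objectness over every anchor/cell (positives carry their
detached CIoU as the target, scale-balanced 4/1/0.4), and binary
cross-entropy classification at positives, with gains
`box/obj/cls = 0.05/1.0/0.5` by default. Targets are assigned to every
(scale, anchor) whose width/height ratio to the target is within
`anchor_t = 4`, at the cell containing the box center; a target that
matches nothing is assigned its best-ratio anchor so nothing is ever
dropped. The neighbour-cell variant (two extra cells per target) is
implemented but off by default: at the small problem sizes this package
targets it slowed convergence in our runs. The box decode is
`xy = (2*sigmoid - 0.5 + grid) * stride`, `wh = (2*sigmoid)^2 *
anchor`. Gradients come from the package's autodiff tape and are
verified against central finite differences.

Training is SGD with momentum 0.937, linear warmup, cosine decay to
10% of the peak rate, and optional mosaic augmentation (the
augmentation the original training recipe names). Anchors default to
the standard priors scaled by `img_size / 640`.

### Problem sizes and the desk profile

The published experiment (250 real images, 640×640, batch 32, 300
epochs) ran on data that is not publicly available and at GPU scale.
The package's verification therefore runs at sizes chosen for a single
CPU:

* block-level properties on feature maps of a few thousand elements,
  100 random draws;
* whole-model equivalence on the full 640×640, 7.2M-parameter network,
  4 random images;
* training checks on 16 synthetic 160×160 scenes with a
  `width_multiple = 0.125` model, batch 4, 50 epochs — the "desk
  profile": `lr = 0.02`, box gain 0.5, mosaic off (standard when the
  goal is memorization of a tiny set), evaluation at confidence 0.01.
  Under this profile the detector reaches train-set mAP@0.5 ≈ 0.93–0.96
  across seeds in 3–4 minutes, and fusing the trained model changes
  mAP by less than 0.01 (typically exactly 0).

## The synthetic scene generator

`scene_spec()` / `render_scene()` emulate the study's data regime so
every stage is testable without a download: top-down scenes of a
flower bed with

* blooms drawn as radial petal stars (8–13 petals, radius 18–34 px at
  the default 320-px canvas, yellow with hue jitter and a darker core);
* buds as small green-yellow discs (radius 6–13 px);
* class drawn with P(bud) = 939/1265 ≈ 0.742, the class imbalance of
  the study's annotation counts;
* foliage occluders drawn *after* the flowers with opacity 0.85, with
  each flower's occluded fraction capped at 60% so objects stay
  learnable;
* ground-truth boxes recorded from the rendered pixel support *before*
  occlusion — mirroring how a human annotator outlines a partially
  covered flower — hence exactly tight by construction;
* a low-light mode multiplying luminance by 0.3–0.6 (the qualitative
  "weak light" regime), additive Gaussian noise, and an optional
  clustering knob for flower placement (real beds are clustered, but
  cluster statistics are not knowable from the source; the knob makes
  no fidelity claim).

Generation is byte-deterministic given `spec$seed`. What passing tests
on these scenes do show: the full pipeline — rendering, label I/O,
letterboxing, target assignment, optimization, decoding, NMS, PR/mAP —
is wired correctly and can drive a detector to memorize a small scene
set. What they do not show: detection accuracy on real chrysanthemum
photographs, whose texture, lighting and clutter the generator does not
model. The headline accuracy of the original study is not reproducible
here and the package does not claim it.

## Evaluation

`average_precision()` ranks detections by confidence, matches greedily
(best-IoU unmatched same-class ground truth in the same image, IoU ≥
threshold, ties on IoU broken by ground-truth index), and integrates
the precision envelope over recall with all-points interpolation — the
discrete realization closest to the continuous area under the PR curve
(not the older 11-point average). mAP@0.5:0.95 averages the 10
thresholds 0.5, 0.55, …, 0.95. Precision and recall at zero
denominators are defined as 0 and flagged; "true negatives" are
undefined for detection and never computed. The implementation is
tested against an independent brute-force evaluator that rescans
confidence thresholds and rematches from scratch.

## Numerical notes and limitations

* All computation is double precision; there is no float32 path.
* BN training mode uses biased batch variance for normalization and
  unbiased updates for the running variance.
* NMS is exact greedy suppression; at the problem sizes involved the
  O(n²) IoU loop is not a bottleneck.
* `predict()` letterboxes to the configured input size; boxes map back
  to original pixels within 1 px.
* Training on one CPU is practical up to a few hundred small images at
  reduced width; the full-width 640-px configuration forward-passes in
  seconds per image but is not a realistic training target without a
  GPU-scale budget.
* Checkpoints are plain serialized R lists of named weight arrays plus
  the config and mode flag; fused and multi-branch checkpoints both
  round-trip.
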