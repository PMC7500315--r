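---
title: "Bilinear pooling for fine-grained histopathology classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilinear pooling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fastbcnn)
```

## The problem

Histopathology subtype classification is a fine-grained problem: the eight
benign/malignant breast-tumor subclasses of a BreaKHis-style dataset differ
in subtle local texture, not in the position of a single salient object.
Lesions are small and widespread, so a useful representation should respond
to *what textures occur* in an image and be indifferent to *where* they
occur. Ordinary CNN heads (global average pooling over a feature map)
capture first-order channel statistics; bilinear pooling captures
second-order channel co-occurrence while discarding all spatial layout.

## The model

A feature extractor \(f\) maps an image to a feature map with \(D\)
channels over \(H' \times W'\) locations. Bilinear pooling forms, at each
location \(l\), the outer product of the two streams' channel vectors and
sum-pools it over locations:

\[ \Phi(I) = \sum_{l} f_A(l)\, f_B(l)^{\top} \in \mathbb{R}^{D_A \times D_B} \]

flattened row-major into a descriptor of length \(D_A D_B\). Because the
sum runs over all locations, the descriptor is *orderless*: any spatial
permutation of locations leaves it unchanged (tested property). The
two-stream model is the quadruple \((f_A, f_B, P, C)\); the **fast**
single-stream variant is the triple \((f, P, C)\) in which one feature map
is pooled against itself — an exact reduction of the two-stream model with
shared weights (tested to 1e-6), with one backbone pass instead of two and
strictly fewer parameters.

The descriptor is passed through the elementwise signed square root
\(\operatorname{sign}(x)\sqrt{|x|}\) (tempering its heavy-tailed scale),
L2-normalized, and classified by a single affine layer with softmax. The
classifier is a single affine map because nothing richer is needed on a
\(D^2\)-dimensional normalized descriptor, matching the bilinear-CNN
lineage.

Squeeze-and-excitation (SE) channel attention can be inserted after any
backbone stage: the squeeze is the per-channel spatial mean
\(s_c = \frac{1}{H W}\sum_{i,j} u_c(i,j)\); the excitation is a bias-free
two-layer gate \(e = \sigma(W_2\,\delta(W_1 s))\) with \(\delta\) = ReLU and
reduction ratio \(r\); the map is rescaled channelwise by \(e\). With zero
gate weights \(e \equiv 0.5\) exactly — a useful analytic test point.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| pooling | `"sum"` | sum-pooling over locations is the defining aggregation; a `"mean"` flag exists for scale stability experiments |
| L2 floor `eps` | `1e-12` | zero vectors map to zero, never NaN |
| SE reduction `r` | 16 in `se_params()` (4 for tiny backbones) | the original SE convention; tiny stage widths (8/16) need a smaller divisor |
| SE bias | none | the gate is exactly \(\sigma(W_2 \delta(W_1 s))\) |
| classifier | affine + softmax | see above |
| tiny backbone | 3 conv stages, 3x3 stride 2, widths 8/16/D | desk-scale experiments must not require multi-million-parameter networks |

Initialization is He-uniform with zero biases, fully seeded. The SE gate's
first layer is drawn nonnegative: squeezed descriptors are nonnegative
after ReLU stages, so a symmetric draw can leave *every* hidden gate unit
dead when \(C/r\) is small (1–4 at tiny scale), silencing SE gradients
permanently; the nonnegative draw guarantees live units at initialization
without constraining training.

## Numerical choices

* Bilinear pooling is computed by the algebraic identity
  \(\Phi = X_A X_B^{\top}\) on the \(C \times (H'W')\) matrix views; it is
  tested against a naive per-location triple-loop oracle. All accumulation
  is in R doubles.
* The flattening of \(\Phi\) is row-major (stream-A channel slowest); fixed
  so classifier weights are reproducible across runs and checkpoints.
* Backpropagation is exact except at the signed square root, whose true
  derivative \(1/(2\sqrt{|v|})\) diverges at 0; the implementation floors
  the denominator at \(\sqrt{10^{-4}}\), bounding the factor at 50. The
  forward pass is exact. Gradients are finite-difference-checked away from
  the floor.
* L2-normalization backward uses the exact projection formula with the same
  `eps` floor as forward.
* Backbones reject inputs whose shape differs from their contract rather
  than silently resizing.

## Standard backbones

`backbone_spec()` accepts `resnet50`, `inceptionv3` and
`inceptionresnetv2` (minimum input 197 px, ImageNet-pretrained or random
init), but `build_backbone()` raises an explicit error for them in an
installation without a deep-learning runtime carrying those architectures
and weights — never a silent random substitute. All shipped experiments
use the tiny backbone; the adapters define the contract a runtime-backed
implementation must satisfy (feature maps of the documented width, no
fully connected head).

## Data pipeline

`scan_layout()` reads a `class/subclass/<mag>X` image tree (BreaKHis
layout), parsing slide ids from the standard filename convention, and
collects unparseable entries rather than dropping them. Cross-validation
is stratified by label at the image level with per-fold class counts
within ±1 of perfect; the split unit is the image, not the patient —
matching the protocol this package models — and fold indices are 1-based
(R convention). Oversampling duplicates minority-class training rows with
replacement to the majority count and is applied inside training folds
only. Augmentation defaults (flips p = 0.5, shifts up to 10%, rotations up
to 40°) are documented choices where only the transform list is
prescribed; oversampling precedes on-the-fly augmentation.

Training is mini-batch SGD on categorical cross-entropy. The learning-rate
schedule is plateau-based: when the *training* loss has not improved for
`lr_patience_epochs` consecutive epochs, the rate is multiplied by
`lr_factor`, so the rate sequence is exactly
\(\{ \text{lr}_0 \cdot \text{factor}^m \}\). Defaults mirror the
full-scale protocol (lr 0.1, batch 16, factor 0.1, patience 10); momentum
defaults to 0 and the epoch budget / minimum rate (100 / 1e-5) are this
package's choices where the stopping rule is otherwise unspecified.

## The synthetic generator

The generator emulates the *statistical* structure that motivates
orderless pooling: class identity carried entirely by small texture motifs
at uniformly random positions (verified by a chi-square uniformity test of
motif centers), over several pseudo-magnification scales that rescale
motif radius and texture wavelength together. Defaults: 4 classes
distinguished by stripe orientation (0°, 90°, 45°) and a spot lattice, 60
motifs of radius 8 px with wavelengths 6–7 px on a 64 px dark field,
scales 100/150/200, seeded end-to-end (byte-identical regeneration).

Two aspects are deliberate departures from real histology and bound what
passing tests can show. First, the field is dark with bright motifs:
during development the original pale-background design left L2-normalized
bilinear descriptors dominated by a constant illumination component
(between-class distance equal to within-class distance at initialization),
which makes the 10-epoch desk-scale task unlearnable for *any* head; real
pipelines escape this via ImageNet-pretrained features, which are out of
scope here. Second, classes share identical color, motif density and
placement statistics, so no first-order shortcut exists by construction —
real subtypes differ in many correlated ways. Passing the capability test
therefore demonstrates that the implementation can learn location-free
second-order texture structure end-to-end; it does not certify accuracy on
real stained tissue.

## Desk-scale experiments

`run_capability_study()` is the package's end-to-end experiment: 160
synthetic images (4 classes x 40, three scales), split 100 train / 60
test, a tiny fast bilinear model (D = 16, 4 740 parameters) against a
GAP-head baseline whose final stage is widened to match that budget within
10% (4 674). Both train 10 epochs under the desk profile — SGD, lr 0.05,
momentum 0.9, batch 8 — calibrated once as the setting where *both* models
train stably from random initialization, so the comparison is meaningful;
results are averaged over 3 model seeds. The same driver reports per-scale
test accuracy of the mixed-scale-trained model, the desk-scale analogue of
magnification-independent evaluation. Problem sizes were chosen so the
whole study runs in a few minutes on one CPU.

## Interpretability

`grad_cam()` backpropagates a chosen class logit to a convolutional layer
(default: the map feeding the pooling head), uses the spatial mean of the
gradient as channel weights, and returns the ReLU of the weighted channel
sum, max-normalized; all-zero maps stay all-zero. For two-stream models
the stream heatmaps are averaged (the reduction is unspecified upstream;
averaging is symmetric). Upsampling to input resolution is bilinear.
`activation_maps()` exposes per-channel first-layer activations, min-max
scaled per channel, to compare the two streams of a two-stream model.

## Known limitations

* No deep-learning runtime: the three standard backbones are contracts,
  not runnable models, and ImageNet transfer is an explicit error.
* The training engine is plain R; it is exact and fully seeded but suited
  to desk-scale problems (tens of thousands of parameters, 64 px images),
  not to full-dataset experiments.
* t-SNE is an exact O(n²) implementation, fine for hundreds of points.
* FPS measurements are hardware-dependent and informational only; only
  the *direction* (single stream at least as fast as two streams) is
  tested.
* Image-level (not patient-level) fold stratification mirrors the modeled
  protocol; it permits slide-level leakage on real data. Group-aware
  splitting can be layered on `make_folds()` by filtering manifests per
  slide before assignment.
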