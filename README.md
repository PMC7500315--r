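# fastbcnn

Fine-grained classification of histopathology-style images with bilinear
convolutional networks, in R.

Subtype classification of stained tissue (e.g. the eight benign/malignant
breast-tumor subclasses of a BreaKHis-style dataset) is *fine-grained*:
classes differ in subtle, small, widely scattered texture, not in the
position of one salient object. This package implements the
representation built for that regime — **bilinear pooling** — together
with the full surrounding pipeline, for researchers who want a tested,
fully seeded, CPU-scale reference implementation.

## The method

A backbone CNN `f` maps an image to a feature map with `D` channels over
`H' × W'` locations. Bilinear pooling aggregates the outer products of the
per-location channel vectors of two streams,

    Φ(I) = Σ_l f_A(l) f_B(l)ᵀ          (D_A × D_B, flattened row-major)

so the descriptor records channel co-occurrence and discards all spatial
layout ("orderless" features — translation-invariant by construction).
The **fast** variant pools one feature map against itself, `Φ = Σ_l f(l)
f(l)ᵀ`: an exact reduction of the two-stream model with shared weights,
with one backbone pass and strictly fewer parameters. The descriptor is
passed through the signed square root `sign(x)·√|x|`, L2-normalized, and
classified by an affine layer with softmax. Squeeze-and-excitation channel
attention (`s_c = mean of channel c`, `e = σ(W₂ relu(W₁ s))`, channels
rescaled by `e`) can be inserted after any backbone stage.

Everything is implemented with exact manual backpropagation (there is no
deep-learning runtime dependency), so models train end-to-end from image
labels on one CPU. The three standard large backbones (ResNet50,
InceptionV3, InceptionResNetV2) are defined as contracts and raise an
explicit error without a runtime that provides them; all shipped
experiments use a small trainable 3-stage backbone.

Also included: BreaKHis-style directory scanning into manifests,
stratified k-fold cross-validation with training-fold oversampling,
seeded augmentation, ROC/AUC (threshold sweep, trapezoidal), an exact
t-SNE for feature embeddings, Grad-CAM heatmaps, and a seeded synthetic
texture-image generator whose class signal is carried by small motifs at
uniformly random positions — the statistical structure orderless pooling
is meant to exploit.

## Worked example

```r
library(fastbcnn)

# the defining operation, on a 2-channel map over two locations
A <- array(0, c(2, 2, 1)); A[, 1, 1] <- c(1, 3); A[, 2, 1] <- c(2, 4)
B <- array(0, c(2, 2, 1)); B[, 1, 1] <- c(5, 7); B[, 2, 1] <- c(6, 8)
matrix(bilinear_pool(A, B), 2, 2, byrow = TRUE)
#>      [,1] [,2]
#> [1,]   17   23
#> [2,]   39   53

# end-to-end desk-scale study: tiny fast bilinear model (D = 16) vs a
# parameter-matched global-average-pooling baseline on the synthetic
# 4-class texture dataset (100 train / 60 test, 64 px, 3 scales,
# 10 epochs, 3 model seeds) — a few minutes on one CPU
res <- run_capability_study(seed = 2024)
res$fast_parameters; res$gap_parameters
#> [1] 4740
#> [1] 4674
cat("fast", res$fast_accuracy, "gap", res$gap_accuracy,
    "auc", res$fast_macro_auc, "max scale drop", res$max_scale_drop, "\n")
#> fast 1 gap 0.7944444 auc 1 max scale drop 0
```

The fast bilinear model solves the held-out texture task (100% over 3
seeds, macro AUC 1) while the first-order baseline with the same
parameter budget averages 79.4%; accuracy is unchanged on every held-out
pseudo-magnification scale after mixed-scale training. The margin is the
point: the classes differ only in second-order texture statistics at
random positions, which average-pooled features capture poorly.

A thin CLI over the same functions ships in `inst/cli/fastbcnn.R`
(`synth`, `manifest`, `folds`, `params`, `train`, `cv`, `eval`,
`gradcam`).

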