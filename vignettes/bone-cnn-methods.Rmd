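---
title: "Bone-CNN: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-CNN: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Primary bone tumours span nine benign and malignant subtypes whose
radiographic appearances overlap; subtype identification drives biopsy,
surgical planning and oncology referral. Bone-CNN is a lightweight
convolutional network for nine-way classification of single-view bone
radiographs, designed so that the parameter budget (about 1.55 million
trainable weights in this implementation) and the arithmetic cost stay far
below generic backbones while retaining multi-scale lesion sensitivity.
This package implements the architecture and its complete training and
evaluation protocol in R, with the convolution, depthwise-convolution and
batch-normalisation kernels compiled via Rcpp/RcppArmadillo (im2col plus a
BLAS GEMM for standard convolutions) and everything else in plain R.

## The architecture

`arch_config()` describes the layer graph declaratively and
`build_bone_cnn()` realises it:

* **Stem** — two 3×3 convolutions (3→32→64 channels), each followed by
  batch normalisation and ReLU, at full input resolution; output
  64×224×224 for the default 224-pixel input.
* **RDSB-1, RDSB-2** — residual depthwise separable blocks
  (64→128 and 128→256, both stride 2): depthwise 3×3 → BN → ReLU →
  pointwise 1×1 → BN, added to a projection shortcut (1×1 convolution with
  matching stride, plus BN), then ReLU. Output sizes 128×112×112 and
  256×56×56.
* **RSB-3** — a plain 1×1 refinement block (256→256, conv → BN → ReLU).
* **MSFA** — parallel 1×1/3×3/5×5 branches (each 256→128, conv → BN →
  ReLU, "same" padding), concatenated to 384 channels and fused by a 1×1
  convolution to 256.
* **Head** — global average pooling, a 512-unit ReLU layer, dropout
  (p = 0.3) and a final fully connected layer with one unit per class.
  Softmax is applied only at prediction time; the loss consumes logits.

Where the published description leaves details open we fixed them once:
normalisation/activation ordering inside the separable blocks follows the
stem's stated conv→BN→ReLU pattern; the residual shortcut across a
channel- or resolution-changing block must be a projection (identity is
impossible across 64→128 stride 2); stride 2 sits on the depthwise
convolution, keeping the pointwise 1×1 cheap; RSB-3 carries no shortcut
("a final 1×1 convolutional block"); convolutions followed by BN carry no
bias (redundant under the affine normalisation), while the fully
connected layers do. Batch normalisation uses the biased (population)
variance for both normalisation and the running statistics (momentum 0.1,
eps 1e-5).

## Complexity accounting

`count_parameters()` and `count_macs()` are closed-form walks over the
layer list (`k²·C_in·C_out·H_out·W_out` per standard convolution,
`k²·C·H_out·W_out` depthwise, `n_in·n_out` per dense layer; BN/ReLU/pool
are not counted). `count_macs_measured()` recomputes the totals from
shapes observed during an instrumented forward pass and must agree
exactly; `profile_model()` reports both, plus FLOPs under the 2×MACs
convention. The default nine-class model counts 1,553,769 trainable
parameters. The published figures for this architecture are 1.52 M
parameters in one place and 1.9 M in another; our count lies between the
two and below the 1.9 M bound. The published 0.48 GFLOPs cannot be
reconciled with a 64-channel stem at full 224² resolution plus a 5×5
branch at 56² (closed form: 5.50 GMACs ≈ 11.0 GFLOPs at 2×MACs), so the
profile records the published number with a non-reproducibility flag
rather than asserting it.

## Preprocessing and augmentation

Radiographs are loaded from PNG (8- or 16-bit, RGB converted to
luminance), resized anisotropically to the square target with bilinear
interpolation — the study's stated behaviour, which distorts anatomical
proportions of non-square images — replicated to three channels and
standardised with the ImageNet statistics (mean 0.485/0.456/0.406, sd
0.229/0.224/0.225).

Class imbalance is addressed by augmentation only. The transform family
(CLAHE; rotation within ±12°; horizontal flip with probability 0.5;
per-axis translation strictly below 5%; gamma correction) is applied in
that fixed order — contrast first so that geometric interpolation does not
smear histograms — with edge-replicating borders for the geometric
operations so the network cannot key on synthetic black wedges. The gamma
range defaults to [0.8, 1.2], a "slight" perturbation preserving
mineralisation patterns; each augmented copy draws every transform.
CLAHE is implemented in full (per-tile clipped 256-bin histograms,
uniform redistribution of the clipped mass, bilinear interpolation of the
tile mappings) because the oracle property we test — one tile with
unlimited clipping equals global histogram equalisation — requires exact
control over the tile and clipping semantics. `plan_class_balancing()`
spreads `target − current` copies as evenly as possible over each class's
original training images (multiplicities differ by at most one);
`materialize_augmented_set()` writes the copies to disk before training,
mirroring the fixed augmented counts of the study's working dataset, and
refuses to touch validation or test records.

## Splitting

`stratified_split()` assigns 70/20/10 per class: floor(n·f) to train and
validation, the remainder to test, then single records move from
over-full to under-full subsets (largest fractional remainder first)
until every subset is within one record of n·f. The published per-class
table is not the output of any single rounding rule — its C2 row floors
where its C8 row rounds up — so the package asserts the ±1 stratification
property rather than cell-exact equality, and ships the published
distribution as a data constant (`bone_tumor_class_distribution()`) for
arithmetic checks and as default augmentation targets. Splitting happens
at image level (the source data has no patient identifiers) on original
images before augmentation, so augmented copies can never leak into
validation or test.

## Training

`train_config()` carries the study protocol: Adam (β₁ 0.9, β₂ 0.999),
initial learning rate 1e-4, cosine annealing with warm restarts, batch
size 8, at most 60 epochs, early stopping with patience 8 on validation
loss (any decrease resets the counter), categorical cross-entropy on
logits. The restart schedule's period parameters are unpublished;
defaults are a first cycle of 10 epochs, period doubling and a zero
learning-rate floor, all configurable, with one scheduler step per
epoch. The best (lowest validation loss) epoch's weights are kept and
restored. All randomness — weight initialisation (He-normal), mini-batch
order, dropout — flows through the R RNG under `config$seed`, so runs are
bit-reproducible. Mixed precision exists only as a configuration flag for
completeness; all computation is double precision. Class weighting is
deliberately absent: balance comes from augmentation alone.

## Evaluation

`evaluate_model()` produces the confusion matrix (rows = truth), per-class
precision/recall/F1/support (zero denominators yield 0 with a warning),
macro and support-weighted F1, one-vs-rest ROC curves and AUCs via the
Mann–Whitney rank statistic with midrank ties, a pooled-pairs micro-AUC
(the pooling construction is our documented choice; the published work
does not define its micro average), accuracy and top-1 error. Argmax ties
break towards the lowest class index so reports are deterministic.
`run_cv()` performs stratified k-fold cross-validation (default k = 5)
with a fresh model per fold and aggregates fold metrics as mean ±
sample sd. `normalized_score()` implements a configurable
accuracy-versus-complexity score, `w·(acc/acc_ref) +
(1−w)·(params_ref/params)` clipped to [0, 1]; the published score column
cannot be reverse-engineered from its printed inputs, so the package's
score is self-describing rather than an attempted reproduction.

## The phantom generator

`generate_phantom()` renders deterministic synthetic radiographs: a
vertical bone band (bright cortices, darker medulla) on a dark background
plus one class-keyed motif per tumour class — sharply marginated lytic
disc with sclerotic rim; moth-eaten lucency cluster; ground-glass matrix
patch (deliberately confusable with the moth-eaten class so confusion
reporting is exercised); exostotic protrusion; sunburst spicules;
onion-skin laminations; expansile remodelling with thinned cortex;
punctate calcifications in a lucency; trabecular striations — followed by
Gaussian blur (σ = 1 px) and additive Gaussian noise (σ = 0.03), clipped
to [0, 1] with lesion contrast 0.35. The defaults were chosen once as
plausible radiograph-like values. Phantoms are separable by construction
(a nearest-centroid probe on raw pixels beats chance comfortably), which
gives downstream training tests a floor; they emulate none of the real
data's acquisition variability, anatomy or label noise, so passing tests
demonstrate that the pipeline's code paths are correct, not that the
reported clinical performance transfers.

## Problem sizes used by the tests

The mechanical tests use a reduced architecture at 8–32 pixels; gradient
correctness is verified against central finite differences. The capacity
checks run the full default architecture at 64 pixels: 32 phantoms must
reach 100% training-set accuracy (read out in inference mode, since the
in-loop training accuracy is noised by dropout and batch statistics)
within 200 gradient steps, and an end-to-end run — 20 phantoms per class,
70/20/10 split, 10 epochs — must beat three times the 1/9 chance rate on
its held-out split. These sizes are the package's chosen smoke scales;
the full 224-pixel, 6631-image protocol is exactly the same code on
larger inputs.

## Known limitations

Single-CPU double-precision training is orders of magnitude slower than
GPU frameworks; the package targets correctness, reproducibility and
desk-scale experiments, not production training speed. No attention
modules, transformer encoders, pretrained-weight loading, explainability
(saliency/Grad-CAM), significance testing or calibration analysis —
these are outside the implemented protocol. Checkpoints are RDS files
with a JSON sidecar describing the architecture.
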