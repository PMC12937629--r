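# boneCNN

Lightweight multi-scale convolutional networks for multi-class
classification of primary bone tumours on radiographs, in R.

Radiographs are the first-line imaging modality for bone lesions, but the
nine primary tumour subtypes (osteosarcoma, chondrosarcoma, Ewing sarcoma,
giant cell tumour, fibrosarcoma, osteoblastoma, osteochondroma,
hemangioma, chordoma) overlap radiographically, and the deep networks that
classify them well are usually too heavy for point-of-care deployment.
**Bone-CNN** is a compact architecture built from:

* a two-layer **stem** (3×3 conv → BN → ReLU, 3→32→64 channels) at full
  resolution — output 64×224×224;
* two **residual depthwise separable blocks** (RDSB): depthwise 3×3 → BN →
  ReLU → pointwise 1×1 → BN, plus a strided 1×1 projection shortcut, then
  ReLU; 64→128 (112×112) and 128→256 (56×56);
* a 1×1 **refinement block** (256→256);
* a **multi-scale feature aggregation** (MSFA) module: parallel
  1×1/3×3/5×5 branches (each 256→128), concatenated (384) and fused by a
  1×1 convolution to 256 — fine texture, medium structure and broad
  context in one stage;
* global average pooling, a 512-unit ReLU layer, dropout *p* = 0.3 and a
  *K*-way linear head (softmax at prediction time only).

The nine-class default counts **1,553,769 trainable parameters
(1.55 M)** and **5.50 GMACs** per 224×224 forward pass (closed form,
confirmed by an instrumented measurement pass).

The package implements the complete study protocol around the
architecture — PNG standardisation (anisotropic bilinear resize, 3-channel
replication, ImageNet normalisation), CLAHE-based class-balancing
augmentation (rotation ±12°, flip, sub-5% translation, gamma), image-level
stratified 70/20/10 splitting with CSV manifests, Adam training (lr 1e-4,
batch 8, ≤60 epochs) with cosine annealing, warm restarts and patience-8
early stopping, full multi-class evaluation (confusion matrix, per-class
precision/recall/F1, one-vs-rest ROC/AUC with macro/micro averages,
top-1 error), stratified 5-fold cross-validation, a complexity profiler,
and a deterministic synthetic radiograph **phantom generator** so every
code path is testable without clinical data. The convolution kernels are
compiled (Rcpp/RcppArmadillo, im2col + BLAS GEMM); training and inference
run on a plain CPU.

## Worked example

Generate a phantom dataset, split it, train briefly and evaluate:

```r
library(boneCNN)

td <- tempfile()
manifest <- generate_dataset(20, phantom_spec(image_size = 64, seed = 1), td)
manifest <- stratified_split(manifest, split_spec(seed = 1))

train <- load_split(manifest, "train", input_size = 64)
val   <- load_split(manifest, "val",   input_size = 64)
test  <- load_split(manifest, "test",  input_size = 64)

set.seed(42)
model <- build_bone_cnn(arch_config(input_size = 64))
fit <- train_model(model, train, val, train_config(max_epochs = 10))
report <- evaluate_model(fit$model, test, train$class_names)
report
```

On this 10-epoch smoke run the report prints:

```
evaluation on 18 records:
  accuracy 0.3889 (top-1 error 0.6111), loss 1.5750
  macro-F1 0.3537, weighted-F1 0.3537, macro-AUC 0.8819, micro-AUC 0.8819
```

i.e. 38.9% held-out accuracy against an 11.1% chance rate after ten
epochs on 126 tiny training images — the phantoms' class motifs are
learnable, and the macro-AUC of 0.88 shows the ranking is already far
better than the hard accuracy suggests. Complexity profiling:

```r
profile <- profile_model(build_bone_cnn(arch_config()))
profile$parameters_millions  # 1.553769
profile$gflops_2x_macs       # 11.001259 at 224x224
```

The same stages are scriptable from a shell via `exec/bone-cnn`
(`phantom | split | augment | train | eval | cv | profile`, YAML config
plus `--section.key=value` overrides).

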