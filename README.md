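# wmcdetr

A lightweight, end-to-end detection transformer for tea pest and disease
imagery, implemented entirely in R. The package targets two field classes —
**tea leaf blight** (irregular brown lesions) and the **green mirid bug**
(small elongated dark insects) — and is built for people who want to study,
test and profile this detector family on a CPU without any external dataset:
every experiment runs on synthetic annotated imagery the package generates
itself.

## What is inside

The baseline is an R18-scale real-time detection transformer: a ResNet18
backbone feeding a hybrid encoder (a transformer layer on the stride-32
level plus convolutional cross-scale fusion) and a 3-layer decoder with
deformable cross-attention, 300 object queries, denoising queries and no
NMS. The lightweight variant swaps in three modules:

- **WTConv** — convolution on Haar wavelet subbands. One level of the
  orthonormal transform halves the resolution, so a depthwise k×k kernel at
  level ℓ sees a 2^ℓ·k receptive field at a fraction of the dense cost.
  Closed-form stage costs are exposed as `flops_wt()`, `flops_bands()`,
  `flops_iwt()`.
- **M2SA** — a three-branch attention block on the top level: dilated
  depthwise gating (rates 1/3/5), multi-head attention with keys/values from
  the multi-scale features, and squeeze-excitation channel attention, summed.
- **CSRFPN** — a context-guided neck: all levels pooled to a common coarse
  grid and refined by rectangular self-calibration (axial pooling + strip
  convolutions), then re-injected top-down through interpolation-based and
  hard-sigmoid-gated fusion.

Around the models: a synthetic fixture generator with the deterministic
8-variant augmentation menu and a leakage-safe 0.7/0.2/0.1 split, YOLO-txt
and COCO-JSON annotation I/O, COCO-style evaluation (greedy matching,
precision/recall/F1, 101-point mAP50 and mAP50:95), Hungarian matching and
GIoU, a desk-scale AdamW training loop, and an analytic architecture
profiler with a hook-based cross-check. Everything runs through the
package's own reverse-mode autodiff engine with compiled convolution
kernels.

## A worked example

Build the full lightweight variant and profile it at the reference
640×640×3 input:

```r
library(wmcdetr)
m <- build_model(model_config(variant = "full"), seed = 1)
print(profile_model(m, 640))
#> model profile @ 640 x 640
#>   params: 13.01 M   flops: 33.9 G   size: 26.0 MB
#>   backbone      4.98 M    15.8 G
#>   encoder       4.31 M     9.1 G
#>   decoder       3.72 M     9.1 G
```

Parameters are counted exactly; FLOPs use a 2-ops-per-multiply-accumulate
convention at the given input size; "size" assumes half-precision weights
(2 bytes each). The baseline variant profiles to 19.86 M / 56.0 G on the
same conventions, so the full model carries roughly a third fewer weights
and 40% fewer operations.

Generate a small annotated dataset, expand it with the deterministic
augmentation menu, and split it without source leakage:

```r
recs <- generate_base_images(10, size = 128, seed = 7)
man  <- split_dataset(augment_expand(recs, factor = 8, seed = 7), seed = 7)
print(man)
#> <dataset_manifest 80 records; train=56 val=16 test=8>
write_annotations(man, "yolo-txt", "fixtures/")
```

Each source image contributes all eight of its augmented variants to a
single split, and 160 sources reproduce the 1280 = 896/256/128 study
layout. The evaluation utilities work on plain data frames:

```r
average_precision(c(TRUE, FALSE, TRUE), 2)   # ranking TP, FP, TP; 2 objects
#> 0.8349835
giou(c(0, 0, 10, 10), c(10, 0, 20, 10))      # touching boxes
#> 0
```

Training and prediction follow the same surface (`train()`,
`predict_boxes()`, `evaluate_detections()`); the test suite overfits the
full variant on eight 64×64 synthetic images as its end-to-end pipeline
check. A thin command line wraps the same functions:

```sh
inst/cli/wmc fixtures --n 160 --factor 8 --out data/ --seed 7
inst/cli/wmc profile  --variant full --size 640
```

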