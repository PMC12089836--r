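---
title: "Methods: a lightweight wavelet-convolution detection transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight wavelet-convolution detection transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model family

Tea plantations are monitored for two visually distinct targets: *tea leaf
blight* (irregular brown lesions spreading over the leaf surface) and the
*green mirid bug* (a small, elongated, dark insect). Field photographs mix
dense and sparse infestations with frequent occlusion and overlap, which is
hard for anchor-based detectors that rely on non-maximum suppression (NMS) to
untangle overlapping candidate boxes.

`wmcdetr` implements an end-to-end, NMS-free detector of the real-time
detection-transformer (RT-DETR) family. The baseline follows the standard
R18-scale recipe:

* a **ResNet18 backbone** (7x7 stem, four stages of two BasicBlocks)
  producing a feature pyramid P3/P4/P5 at strides 8/16/32 and widths
  128/256/512;
* a **hybrid encoder**: a transformer encoder layer applied only to the top
  level (attention-based intra-scale feature interaction, AIFI) and a
  convolutional cross-scale fusion neck (CCFF, an FPN+PAN of CSPRep blocks);
* a **decoder** of three layers with query self-attention, multi-scale
  deformable cross-attention and per-layer classification/box heads; 300
  object queries are selected from the encoder tokens, boxes are refined
  iteratively in normalized `cxcywh` space, and 100 denoising queries built
  from noised ground-truth boxes stabilise training.

The lightweight variant replaces three of these components:

1. designated backbone 3x3 convolutions by **WTConv** (wavelet-transform
   convolution),
2. the AIFI attention sublayer by **M2SA** (multiscale multihead
   self-attention),
3. the CCFF neck by **CSRFPN** (context-guided spatial feature
   reconstruction).

Every variant of the ablation grid (`baseline`, `wtconv_only`, `m2sa_only`,
`wtconv+m2sa`, `csrfpn_only`, `full`) is constructable through
`model_config()`, and the analytic profiler reports parameters and FLOPs for
each.

## Wavelet-transform convolution

A single level of the orthonormal 2-D Haar transform maps a map $x$ to four
half-resolution subbands; on each $2\times 2$ block with entries
$p, q$ (top row) and $s, t$ (bottom row):

$$\mathrm{LL} = \tfrac{p+q+s+t}{2},\quad
  \mathrm{LH} = \tfrac{p-q+s-t}{2},\quad
  \mathrm{HL} = \tfrac{p+q-s-t}{2},\quad
  \mathrm{HH} = \tfrac{p-q-s+t}{2}.$$

The transform is orthonormal, so it conserves energy and the synthesis
(`haar_idwt2()`) is its exact transpose-inverse. WTConv decomposes the input
over $\ell$ levels (recursing on the unconvolved LL band), applies a small
depthwise $k\times k$ convolution to every subband of every level, sums the
convolved LL of each level into the reconstruction cascade, and adds a
full-resolution depthwise base convolution. A level-$\ell$ band kernel acts
on a grid decimated $2^\ell$-fold, so the operator reaches a
$2^\ell k$-pixel receptive field at a small fraction of the cost of a dense
convolution of that size.

The closed-form cost of the three stages (decomposition, per-band
convolution, reconstruction) is available as `flops_wt()`, `flops_bands()`
and `flops_iwt()`. `flops_bands()` is written with the full
$C_{in}\times C_{out}$ product, as the closed form defines it; the shipped
operator is depthwise followed by a 1x1 pointwise mix, and the model
profiler counts that actual depthwise cost (plus the closed-form
decomposition/reconstruction terms, which are negligible at model scale).
Both conventions are deliberately present and documented - one is the
analytic definition, the other the cost of the implementation.

**Placement policy.** Which backbone convolutions become WTConv is a policy
choice (`wt_policy` in `model_config()`). The shipped default (`"balanced"`)
replaces both convolutions of every block in stages 2-3 and the final
stage-4 block, keeping the first high-resolution stage and the stage-2 entry
(strided) convolution dense. The published description of this architecture
family does not pin the placement, the level count or the kernel sizes, so
these defaults were fixed once by calibrating the detector-level
parameter/FLOP totals to the reference architecture scale (see *Profiler
calibration* below): $\ell = 2$ levels, band kernel $k = 3$, base kernel 5.
At small input sizes the per-layer level count is clamped so the smallest
decomposed map stays at least $2\times 2$ (a layer where no level fits stays
dense); `wtconv2d()` itself errors instead, naming the limiting level.

## Multiscale multihead self-attention (M2SA)

M2SA runs three parallel branches on the projected P5 map
$X \in \mathbb{R}^{C\times H\times W}$ and sums them:

* **Multi-scale gating:** a 1x1 convolution reduces channels to $C/4$; three
  depthwise 3x3 convolutions with dilation rates $\{1, 3, 5\}$ are summed; a
  1x1 convolution restores $C$ channels; the result gates the input
  elementwise, $X_{msa} = g(X) \odot X$.
* **Attention:** queries come from the input tokens, keys and values from
  the multi-scale features ($K$/$V$ optionally spatially downsampled;
  ratio 1 by default since the top level is only 20x20 at a 640 input);
  standard multi-head scaled dot-product attention follows.
* **Channel attention:** global average pooling, a squeeze-excitation
  bottleneck (reduction 16, ReLU6 inside, sigmoid outside) and a per-channel
  multiplicative gate.

The written form of the multi-scale branch can be read as multiplying by
$X$ twice (once in the fusion equation and once in the output equation). The
default here is a **single** gating, matching the semantics of the
squeeze-style designs this block descends from; `m2sa_config(literal_eq6 =
TRUE)` switches to the literal double product. With all weights zero the
block collapses to exactly $0.5\,X$ (zero multi-scale gate, zero value
projection, sigmoid(0) channel gate), which the tests assert bit-exactly.

Inside the encoder layer (M2SA-AIFI) the 2-D sine-cosine position embedding
is added to the tokens entering $Q$ and $K$ only, and the feed-forward
sublayer (width 1024), residual connections and layer normalization of the
standard AIFI layer are retained. The layer applies to P5 only; requesting
it on a lower level is an error by contract.

## Context-guided spatial feature reconstruction (CSRFPN)

The neck replaces CCFF with four cooperating pieces, wired as

```
context = PCE(P3, P4, P5)
N5 = RCM(DIF(P5, context))
N4 = RCM(MFF(P4, N5))
N3 = RCM(MFF(P3, N4))
```

* **RCM** (rectangular self-calibration): axial average pooling gives a row
  vector and a column vector whose broadcast sum forms a rectangular
  attention region; a 1xk strip convolution, normalization + ReLU, a kx1
  strip convolution and a sigmoid calibrate it; the attention multiplies a
  depthwise 3x3 transform of the input.
* **PCE** (pyramid context extraction): the three levels are average-pooled
  by factors 8/4/2 to a common grid (H/64 x W/64), concatenated, fused by a
  1x1 convolution and refined by a stack of RCMs.
* **DIF** (dynamic interpolation fusion): bilinear resize, 1x1 channel
  alignment, elementwise addition.
* **MFF** (multi-feature fusion): a hard-sigmoid gate
  $\mathrm{hsig}(t) = \mathrm{clamp}(t+3, 0, 6)/6$ computed from the
  low-resolution map, upsampled and multiplied into a convolution of the
  high-resolution map.

The published figure for this neck is schematic, so the wiring above is
fixed by this package and documented as an interpretation: the pooled
context enters at the top level through DIF, a top-down MFF cascade follows,
and an RCM sits at every level. Open choices were resolved once, jointly
with the profiler calibration: strip kernel 9; two stacked RCMs in PCE with
2-group (channel-mixing) strip convolutions, while the per-level RCMs use
depthwise strips; the MFF high-resolution convolution is 3x3 with 2 groups
and the gate convolution is a dense 3x3. Bilinear interpolation uses
half-pixel-centre alignment everywhere so results are reproducible across
implementations.

## Decoder, loss and training harness

Query selection scores every encoder token by its maximum class logit
(tokens whose grid anchor leaves the unit box are masked out) and keeps the
top 300 (or the token count, if smaller). Reference boxes come from the
anchor plus a predicted offset; the decoder refines them layer by layer with
detached references, the standard stabilisation for this family. Deformable
cross-attention uses 8 heads, 4 sampling points and all 3 levels, with the
ring-shaped offset-bias initialisation.

Training minimises the usual DETR combination per decoder layer and for the
encoder proposals: binary cross-entropy classification (normalised by the
ground-truth count), an L1 box term (weight 5) and a GIoU term (weight 2) on
Hungarian-matched pairs, with matching costs 2/5/2
(classification/L1/GIoU). Denoising queries (groups of positively and
negatively noised ground-truth boxes; box noise 0.4, label noise 0.25) train
with their known assignment, positives to their object and negatives to
background, and an attention mask keeps the matching queries blind to the
denoising groups and the groups blind to each other. The optimizer is AdamW
(learning rate 1e-4, weight decay 1e-4, batch 4 by default, per the
reference training configuration), with global-norm gradient clipping at
0.1. A non-finite loss aborts and returns the last finite state.

All of this runs on the package's own reverse-mode autodiff engine (an R
tape over compiled im2col/GEMM convolution kernels). Channel normalization
uses per-map (instance) statistics in both training and evaluation rather
than batch statistics: with per-image gradient accumulation there is no
batch axis, instance statistics keep every layer's activations scaled
identically at train and test time, and the parameter count (one scale and
one shift per channel) is unchanged. This is a deliberate, documented
departure from batch-norm semantics and one reason the desk-scale training
results should not be read as a reproduction of GPU training.

## Profiler conventions and calibration

`profile_model()` counts parameters exactly (every trainable scalar) and
FLOPs analytically at a reference input size with a **2 ops per
multiply-accumulate** convention: convolutions cost
$2 k^2 C_{in} C_{out} H_{out} W_{out} / \text{groups}$ (+ bias adds), linear
layers $2 n_{in} n_{out} n_{tokens}$, attention both its projections and the
$QK^T$/$AV$ products; normalizations, activations, poolings and bilinear
resampling are not counted (they are three orders of magnitude below the
convolution terms at this scale). The serialized size assumes half-precision
storage, 2 bytes per weight. An independent check runs a real forward pass
with an op-level FLOP meter inside the engine; the test suite requires
agreement within 1%.

The free architectural knobs - WTConv placement/levels/kernels and the
CSRFPN kernel/grouping choices above - were set **once** so that the
analytic profiles of the three headline variants land on the reference
architecture scale (about 19.9 M / 56.9 G for the baseline, 13.9 M / 42.6 G
with the WTConv backbone, 12.8 M / 33.9 G for the full model at a 640x640x3
input), and are not revisited. `scripts/acceptance.R` recomputes the full
and WTConv-only FLOP totals from scratch at every run.

## The synthetic fixture generator

No field imagery ships with the package, so `generate_base_images()` draws
annotated scenes that emulate the study design: a textured green background
(low-frequency illumination plus pixel noise), 1-12 objects per image,
blight lesions as irregular brown radial blobs of at least 2% image area,
mirid bugs as elongated dark blobs below 1%, and a fixed share of
multi-object images with a deliberately overlapping pair to emulate
occlusion. `augment_expand()` applies the deterministic eight-variant menu -
original, horizontal flip, vertical flip, three right-angle rotations,
Gaussian noise (sigma 10 on the 0-255 scale, clipped), and flip+noise - with
exact box transforms for the geometric variants. Rotation is restricted to
right angles so the box transforms are exact; arbitrary-angle rotation would
require re-fitting boxes and is excluded from the invariant tests.
`split_dataset()` assigns whole source images to train/val/test at
0.7/0.2/0.1, so 160 sources expanded eightfold give exactly 1280 records
split 896/256/128 and augmented siblings can never leak across splits.

What the generator does **not** emulate: real leaf venation and specular
highlights, lighting extremes, camera blur, class-dependent context, or the
long-tailed object statistics of field data. Tests passing on these fixtures
therefore certify the pipeline (geometry, bookkeeping, optimisation,
evaluation), not field accuracy.

## Desk-scale problem sizes

The package's correctness oracles run at sizes a laptop CPU handles
comfortably, chosen as the package's own test design: gradient checks on
maps up to 8x8; wavelet property tests up to 64x64; the dataset-procedure
check generates its 160 sources at 128x128 (the split counts are
size-independent); and the end-to-end overfit oracle trains the full
variant on eight 64x64 images for 200 single-image AdamW steps (peak
learning rate 7e-4 under a 10-step warmup and cosine decay, 60 queries, the
full 100-query denoising budget) and then requires mAP50 of at least 0.9 on
those same images, evaluating every detection with score at least 0.01. Overfitting a handful of images is the
standard smoke test for a detection pipeline: it exercises every stage -
rendering, augmentation, matching, loss, gradients, refinement, decoding,
evaluation - while proving nothing about generalisation.

## Known limitations

* Instance-statistics normalization (see above) in place of batch
  normalization.
* Training is desk-scale only; there is no GPU path, no mosaic
  augmentation (deliberately, matching the detector family), and no
  multi-scale training schedule.
* The profiler's uncounted terms (norms, activations, resampling) make its
  totals a convolution/attention cost model, not a hardware cycle count;
  FPS is reported for information only and never asserted.
* The CSRFPN wiring and several unstated design constants are documented
  interpretations; alternatives are reachable through `neck_config()` and
  `wt_policy` but are not part of the shipped profile.
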