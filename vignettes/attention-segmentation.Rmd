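---
title: "Attention-enhanced encoder-decoder segmentation of ultrasound lesions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-enhanced encoder-decoder segmentation of ultrasound lesions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

B-mode ultrasound images of soft-tissue lesions (the motivating case is
uterine fibroids) are corrupted by multiplicative speckle, offer weak
lesion-to-background contrast, and present lesions at widely varying sizes
and positions. Manual delineation is slow and subjective; automatic binary
segmentation of the lesion region is the task this package addresses. The
package is a complete, self-contained implementation: network, training
loop, metrics, a synthetic phantom generator standing in for clinical data,
and a command-line interface.

## The network

The architecture is a four-stage U-Net-style encoder-decoder with a
one-channel sigmoid head, augmented by three attention blocks. All tensors
follow the `(batch, channel, row, col)` layout; input extents must be
divisible by 8 because the encoder pools three times.

**Encoder.** Stages 1-2 are plain double 3x3 convolution blocks
(convolution, batch normalization, rectifier, twice). Stages 3-4 — where
semantic content is rich but resolution is low — are *multi-receptive
fusion blocks*: a 1x1 convolution unifies the width, then three parallel
3x3 convolutions at dilation rates (1, 3, 5) read receptive fields of
effective side 3, 7 and 11. The branches are coupled: branch 2 consumes the
working features plus branch 1's output, branch 3 additionally consumes
branch 2's. Spatial attention (channel-mean and channel-max maps stacked,
convolved to one channel, sigmoid) refines branches 1 and 3; channel
attention (shared two-layer bottleneck over global average- and max-pooled
descriptors) refines branch 2. The three branch outputs and the working
features are concatenated and fused by a 1x1 convolution, and a final
spatial attention gates the result. 2x2 max pooling sits between stages.

**Skip connections.** Each of the three skip paths is refined by an
*SE skip fusion block*: the deeper decoder stream is bilinearly upsampled to
the skip resolution, the encoder stream passes a 3x3 convolution, the two
are concatenated, and the base features go through two cascaded
squeeze-and-excitation gates, each wrapped in an additive residual
(`x * w + x`) to prevent attenuation. A 3x3 convolution extracts local
features from the second enhancement, and the two enhanced maps plus the
convolution output are densely fused by a 1x1 convolution. Single-path
modes (`input1_only`, `input2_only`) keep the cascade but feed it only the
encoder or only the decoder stream, so path-selection experiments are
configuration changes, not code changes.

**Decoder.** Each decoder stage is a *dual-scale attention block*: the
fused features are processed in parallel at native resolution and at 2x
(bilinearly upsampled) resolution; each scale passes a 3x3 convolution and
channel attention with a shortcut from its pre-attention map; the 2x branch
is folded back to native resolution by exact box averaging and summed with
the native branch; two further convolution+attention stages (channel, then
spatial) refine the fusion.

Every block has an enable flag (`use_mrf`, `use_dual_scale`,
`use_skip_se`), so the ablation baseline and every intermediate
configuration are reachable from `model_config()`.

## Decisions where the design was open

Several structural points admit more than one reading; the package fixes
them as follows and exposes toggles where reasonable:

* **Cross-branch fusion in the multi-receptive block** is elementwise sum —
  it preserves width and matches the residual-style motivation of the
  coupling. The final fusion is concatenation + 1x1 convolution
  (`mrf_fusion = "concat"`), with summation available as a toggle.
* **Skip fusion resolution.** The SE skip block operates at the skip
  (encoder) resolution: the decoder stream is upsampled to it, and the
  encoder stream is used at its native, already-downsampled resolution.
  Pooling the skip further and upsampling the result would discard spatial
  detail for no benefit.
* **Dual-scale fusion resolution.** The 2x branch folds back to native
  resolution before fusion, keeping the decoder's tensor ladder intact; the
  fold-back is a resize-to-shape box average, so odd extents round-trip
  exactly.
* **Channel attention bottleneck** is shared between the average-pool and
  max-pool descriptors (the CBAM convention). The SE gate differs from
  channel attention exactly by the absence of the max-pool path, a
  relationship the tests assert directly.
* **Four encoder stages, three poolings.** Stage 4 doubles as the
  bottleneck; the decoder has three up-steps.
* **No residual from the block input around the dual-scale block** — only
  the within-scale pre/post-attention shortcuts.
* **Skip connections at all three levels**, each SE-fused when enabled.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `stage_widths` | 32, 64, 128, 256 | channels | doubling ladder landing the full model in the low-millions parameter regime; fully configurable |
| `dilations` | (1, 3, 5) | dilation rate | fine detail + mid and wide context without gridding |
| `reduction` | 8 | ratio | attention bottleneck width `C/8`, clamped to >= 1 |
| `spatial_kernel` | 7 | pixels | wide enough to smooth speckle-scale variation in the descriptor maps |
| `upsample_mode` | bilinear | — | smooth interpolation suits speckle imagery; nearest available |
| learning rate | 0.001 | — | Adam default of the training regime |
| epochs / batch | 200 / 16 | — | reference training regime; desk-scale runs override |
| threshold | 0.5 | probability | binarization for metrics and predicted masks |

Weights use He-normal initialization (`sd = sqrt(2 / fan_in)`); batch-norm
scale/shift start at 1/0 with running statistics at 0/1, so an untrained
block in evaluation mode is an identity on its normalized path — the
property the closed-form tests exploit.

## Loss and metrics

Training minimizes the soft Dice loss
`1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)`, averaged per image
over the batch. The smoothing constant is `1e-9`: small enough that the
half-overlap identity `loss([0.5, 0.5], [1, 0]) = 0.5` holds to `1e-9`,
while the empty-vs-empty case still evaluates to a perfect match rather
than 0/0.

Evaluation binarizes at 0.5 and tallies per-image pixel confusion counts;
from `TP, TN, FP, FN` it reports Dice, Matthews correlation, Jaccard,
accuracy and recall. Degenerate denominators follow the standard
conventions (Dice/Jaccard/recall = 1 when there is nothing to find and
nothing found; Mcc = 0 when a marginal is empty). Two aggregations are
provided because dataset-level scores can be computed either way:
`per_image_mean` (average of per-image metrics; the default) and
`global_pool` (metrics of the summed counts). The tests pin the algebraic
couplings `jaccard = dice / (2 - dice)` and `mcc = cor(pred, truth)` on
flattened masks.

## The synthetic phantom generator

`generate_phantoms()` emulates the qualitative challenges of clinical
B-mode imagery: a smooth background echo texture (coarse Gaussian grid,
bilinearly upsampled), one to three elliptical hypoechoic lesions at random
position, rotation and size (semi-axes 5-25 % of the image side),
interior attenuation by `contrast_drop` (default 0.45, a markedly
hypoechoic lesion), unit-mean multiplicative gamma speckle
(`speckle_shape = 4`, moderately strong; Rayleigh available), a 1-pixel
Gaussian point-spread blur, and clipping to [0, 1]. The mask is the exact
rasterized lesion union. Generation is a pure function of the config, so
datasets are bitwise reproducible. An RGB variant with a skin-tone gradient
exists solely to exercise the 3-channel input path.

What the phantoms do **not** model: physically accurate acoustics (no
point-spread anisotropy, attenuation shadows, reverberation or refraction
artifacts), posterior enhancement, heterogeneous lesion interiors, or
anatomical context. Passing tests on phantoms therefore demonstrate that
the architecture, gradients, optimizers and pipeline work end to end and
can overfit a small, well-posed task — they say nothing quantitative about
clinical performance.

## Numerical choices

* **Differentiation** is reverse-mode on an operation tape; convolutions
  are compiled im2col + GEMM kernels (exact double precision, verified to
  `1e-10` against a naive loop oracle), tiled over cache-resident spatial
  strips with channel blocking.
* **Batch normalization** uses biased batch variance in training, running
  statistics (momentum 0.1, `eps = 1e-5`) in evaluation.
* **Resizing** uses half-pixel-centre bilinear interpolation, index
  snapping for nearest, and exact box averaging for downsampling; the 2x
  cases have dedicated fast paths that are bit-identical to the general
  separable-matrix path.
* **Max pooling** breaks ties toward the first element in scan order;
  channel/global max maps record their argmax for exact gradients.
* **Optimizers**: Adam (beta 0.9/0.999), Adamax, RMSprop (rho 0.9),
  Adagrad, SGD, all with `eps = 1e-8` where applicable.
* **Determinism**: every stochastic step (weight init, shuffling, phantom
  generation) flows from explicit seeds; identical configs reproduce loss
  sequences and datasets bit for bit on the same platform/BLAS.

## Desk-scale experiment profiles

The experiment grids enumerate the component studies — 5 module combinations,
21 dilation triples `(1, d2, d3)` with `2 <= d2 < d3 <= 8`, 3 skip-path
modes, 5 optimizers — as configuration enumerations. The package's test and
acceptance runs use a reduced profile chosen to exercise the full
architecture on one CPU: 64x64 phantoms, stage widths (8, 16, 32, 64),
8 training images, 150 full-batch steps for learning-capability checks and
2-4 epochs for pipeline smoke runs. The full-scale profile (256x256,
widths 32-256, 200 epochs, batch 16) is reachable through the same
configuration objects but is intended for accelerator hardware.

## Known limitations

* Training at the reference scale is impractical on one CPU; the package is
  CPU-honest but desk-scale by default.
* Absolute parameter counts depend entirely on the configurable width
  schedule; across architectures only orderings and rough scale are
  meaningful.
* Binary masks only; no multi-class heads, no DICOM ingestion, no boundary
  metrics (Hausdorff-type distances).
* No data augmentation or learning-rate scheduling — none is part of the
  reference regime.
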