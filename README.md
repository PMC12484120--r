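# echoseg

Attention-enhanced encoder-decoder segmentation of hypoechoic lesions in
ultrasound images, as a self-contained R package: the network, its
reverse-mode autodiff engine with compiled convolution kernels, the Dice
training loss, a five-metric evaluation suite, a seeded synthetic
ultrasound-phantom generator, experiment grids and a command-line
interface. No deep-learning framework is required.

## Who this is for

Researchers in medical image analysis who want a transparent, fully
inspectable reference implementation of an attention U-Net variant for
binary lesion segmentation — for studying the architecture's components
(ablations, dilation sweeps, skip-path and optimizer selection) at desk
scale on a CPU, with every numerical step open to inspection and testing.

## The model

A four-stage U-Net-style encoder-decoder `f(x) -> p ∈ (0,1)^{H×W}` over
grayscale or RGB images (extents divisible by 8), with three attention
blocks:

* **Multi-receptive fusion** (encoder stages 3-4): parallel 3×3
  convolutions at dilations (1, 3, 5) — effective receptive sides 3, 7,
  11 — with cross-branch coupling, spatial attention on branches 1 and 3,
  channel attention on branch 2, concatenation + 1×1 fusion, and a final
  spatial gate.
* **SE skip fusion** (all three skips): encoder and upsampled decoder
  streams concatenated, refined by two cascaded squeeze-and-excitation
  gates with additive residuals (`B·w + B`), a 3×3 convolution, and dense
  1×1 fusion of all three maps.
* **Dual-scale attention** (decoder stages): the same features processed
  at native and 2× resolution in parallel, channel-attention enhanced with
  pre/post-attention shortcuts, box-averaged back, and refined by
  channel-then-spatial attention stages.

Training minimizes the soft Dice loss
`L = 1 − (2·Σ pᵢyᵢ + ε)/(Σ pᵢ + Σ yᵢ + ε)`; evaluation reports Dice,
Matthews correlation (Mcc), Jaccard, accuracy and recall from per-image
pixel confusion counts, with
`Dice = 2TP/(2TP+FN+FP)`, `Jaccard = TP/(TP+FN+FP)`,
`Mcc = (TP·TN − FP·FN)/√((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.

Every block has an enable flag, so the plain baseline and all ablation
configurations come from one `model_config()`. See the methods vignette
(`vignettes/attention-segmentation.Rmd`) for the model account, parameter
rationale and design decisions.

## Worked example

Generate speckle-noised phantoms with ground-truth lesion masks, train a
reduced-width full model for 60 steps, and evaluate:

```r
library(echoseg)

phantoms <- generate_phantoms(phantom_config(n_images = 10, size = 64, seed = 42))
splits <- split_samples(phantoms, c(0.8, 0.1, 0.1), seed = 42)
data <- list(train = samples_to_arrays(splits$train),
             val   = samples_to_arrays(splits$val))

fit <- fit_segmentation(
  data,
  model_config(stage_widths = c(8, 16, 32, 64)),
  train_config(epochs = 60, seed = 1)
)
glance(fit)
#> # A tibble: 1 × 5
#>   epochs best_epoch best_val_loss final_train_loss parameters
#>    <int>      <int>         <dbl>            <dbl>      <dbl>
#> 1     60         60         0.465            0.538     359831

report <- evaluate_model(restore_best(fit)$model, data$train)
glance(report)
#> # A tibble: 1 × 7
#>    dice   mcc jaccard accuracy recall n_images aggregation
#>   <dbl> <dbl>   <dbl>    <dbl>  <dbl>    <int> <chr>
#> 1 0.806 0.812   0.721    0.952  0.998        8 per_image_mean
```

`glance(fit)` summarises the fit: 60 epochs (here one full-batch step
each), the checkpointed best-validation epoch, and the exact trainable
parameter count of the reduced-width model. The metric report shows the
model has learned the lesions of its small training set after only 60
steps — Dice 0.81 (binarized overlap at threshold 0.5) with near-complete
recall, as per-image means over the 8 training phantoms; `tidy(report)`
gives the per-image rows and `autoplot(fit)` the loss/accuracy curves.

The same pipeline runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "echoseg", package = "echoseg"))')
Rscript "$CLI" synth   --n-images 16 --size 64 --seed 1 --out-dir data
Rscript "$CLI" train   --data-dir data --seed 1 --out-dir run --set train.epochs=10
Rscript "$CLI" eval    --data-dir data --checkpoint run/checkpoint.rds --split val --out-dir run
Rscript "$CLI" predict --checkpoint run/checkpoint.rds --image-dir data/images --out-dir pred
Rscript "$CLI" grid    --data-dir data --grid modules --out-dir grid --set train.epochs=2
```

`grid` accepts `modules` (5 block combinations), `dilation` (21 triples),
`skip_path` (3 modes) and `optimizer` (5 optimizers) and writes one CSV row
of the five metrics per configuration.

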