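# Network assembly: a four-stage encoder-decoder for binary lesion
# segmentation with per-module enable flags so every ablation configuration
# (baseline, each block alone, all three) is constructible from one config.

#' Architectural configuration
#'
#' Hyperparameter record for [build_model()]. The defaults give the full
#' model: multi-receptive fusion in encoder stages 3-4, dual-scale attention
#' in every decoder stage, and SE skip fusion on every skip connection.
#' Setting all three `use_*` flags to `FALSE` yields the plain double-conv
#' encoder-decoder baseline.
#'
#' @param in_channels 1 (grayscale ultrasound) or 3 (RGB dermoscopy).
#' @param stage_widths Strictly increasing widths of the four encoder stages.
#' @param use_mrf,use_dual_scale,use_skip_se Enable flags for the three blocks.
#' @param dilations Dilation-rate triple of the multi-receptive branches.
#' @param reduction Bottleneck ratio shared by all channel/SE attention.
#' @param spatial_kernel Odd spatial-attention filter width.
#' @param upsample_mode `"bilinear"` or `"nearest"` decoder upsampling.
#' @param mrf_fusion `"concat"` or `"sum"` fusion inside the multi-receptive
#'   block.
#' @param skip_path_mode Path selection of the SE skip fusion block.
#' @return A `model_config` list, validated.
#' @export
model_config <- function(in_channels = 1L,
                         stage_widths = c(32L, 64L, 128L, 256L),
                         use_mrf = TRUE, use_dual_scale = TRUE, use_skip_se = TRUE,
                         dilations = c(1L, 3L, 5L), reduction = 8L,
                         spatial_kernel = 7L,
                         upsample_mode = c("bilinear", "nearest"),
                         mrf_fusion = c("concat", "sum"),
                         skip_path_mode = c("dual", "input1_only", "input2_only")) {
  upsample_mode <- match.arg(upsample_mode)
  mrf_fusion <- match.arg(mrf_fusion)
  skip_path_mode <- match.arg(skip_path_mode)
  if (!in_channels %in% c(1L, 3L)) stop("in_channels must be 1 or 3", call. = FALSE)
  if (length(stage_widths) != 4L || any(diff(stage_widths) <= 0)) {
    stop("stage_widths must be four strictly increasing positive integers",
         call. = FALSE)
  }
  if (length(dilations) != 3L || any(diff(dilations) <= 0) || any(dilations < 1)) {
    stop("dilations must be a strictly increasing triple", call. = FALSE)
  }
  if (spatial_kernel %% 2 == 0 || spatial_kernel < 3) {
    stop("spatial_kernel must be odd and >= 3", call. = FALSE)
  }
  if (reduction <= 0) stop("reduction must be positive", call. = FALSE)
  structure(
    list(in_channels = as.integer(in_channels),
         stage_widths = as.integer(stage_widths),
         use_mrf = isTRUE(use_mrf), use_dual_scale = isTRUE(use_dual_scale),
         use_skip_se = isTRUE(use_skip_se),
         dilations = as.integer(dilations), reduction = as.integer(reduction),
         spatial_kernel = as.integer(spatial_kernel),
         upsample_mode = upsample_mode, mrf_fusion = mrf_fusion,
         skip_path_mode = skip_path_mode),
    class = "model_config"
  )
}

#' Build the segmentation network
#'
#' Encoder: four stages at `stage_widths`; stages 1-2 are double 3x3
#' convolution blocks, stages 3-4 multi-receptive fusion blocks when
#' `use_mrf` (double-conv otherwise), with 2x2 max pooling between stages.
#' Decoder: three up-steps; each fuses the skip and deeper features through
#' SE skip fusion when `use_skip_se` (plain bilinear upsample + concatenate
#' otherwise), followed by a dual-scale attention block when `use_dual_scale`
#' (double-conv otherwise). Head: 1x1 convolution + sigmoid to one channel.
#' Parameters are initialised from the current RNG state.
#'
#' @param config A [model_config()].
#' @return An `echoseg_model` object.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  w <- config$stage_widths
  enc_stage <- function(cin, cout) {
    if (config$use_mrf) {
      new_mrf_block(cin, cout, config$dilations, config$reduction,
                    config$spatial_kernel, config$mrf_fusion)
    } else {
      new_double_conv(cin, cout)
    }
  }
  dec_stage <- function(cin, cout) {
    if (config$use_dual_scale) {
      new_dual_scale_block(cin, cout, config$reduction, config$spatial_kernel,
                           config$upsample_mode)
    } else {
      new_double_conv(cin, cout)
    }
  }
  decoder <- list()
  # up-steps from deepest to shallowest: (skip width, deeper width)
  lad <- list(c(w[3], w[4]), c(w[2], w[3]), c(w[1], w[2]))
  for (i in seq_along(lad)) {
    ws <- lad[[i]][1]; wd <- lad[[i]][2]
    decoder[[i]] <- list(
      skip_se = if (config$use_skip_se) {
        new_skip_se_block(ws, wd, ws, config$reduction, config$skip_path_mode)
      },
      block = dec_stage(if (config$use_skip_se) ws else ws + wd, ws)
    )
  }
  model <- list(
    config = config,
    enc1 = new_double_conv(config$in_channels, w[1]),
    enc2 = new_double_conv(w[1], w[2]),
    enc3 = enc_stage(w[2], w[3]),
    enc4 = enc_stage(w[3], w[4]),
    decoder = decoder,
    head = new_conv2d(w[1], 1L, kernel = 1L)
  )
  class(model) <- "echoseg_model"
  model
}

fwd_stage <- function(blk, tape, x, training) {
  switch(blk$kind,
    double_conv = fwd_double_conv(blk, tape, x, training),
    mrf_block = fwd_mrf_block(blk, tape, x, training),
    dual_scale_block = fwd_dual_scale_block(blk, tape, x, training),
    stop("unknown stage kind ", blk$kind)
  )
}

# Full forward pass; returns the sigmoid prediction node (or array when
# untaped). `x` is (batch, in_channels, H, W) with H, W divisible by 8.
fwd_model <- function(model, tape, x, training = FALSE) {
  d <- dim(nval(x))
  if (length(d) != 4L) stop("input must be rank-4 (batch, channel, row, col)", call. = FALSE)
  if (d[2] != model$config$in_channels) {
    stop("model expects ", model$config$in_channels, " input channels, got ", d[2],
         call. = FALSE)
  }
  if (d[3] %% 8 != 0 || d[4] %% 8 != 0) {
    stop("input extents must be divisible by 8 (three 2x2 poolings), got ",
         d[3], "x", d[4], call. = FALSE)
  }
  e1 <- fwd_stage(model$enc1, tape, x, training)
  e2 <- fwd_stage(model$enc2, tape, ag_maxpool2(tape, e1), training)
  e3 <- fwd_stage(model$enc3, tape, ag_maxpool2(tape, e2), training)
  e4 <- fwd_stage(model$enc4, tape, ag_maxpool2(tape, e3), training)
  skips <- list(e3, e2, e1)
  h <- e4
  for (i in seq_along(model$decoder)) {
    dec <- model$decoder[[i]]
    s <- skips[[i]]
    fusedin <- if (!is.null(dec$skip_se)) {
      fwd_skip_se_block(dec$skip_se, tape, s, h, training)
    } else {
      ds <- dim(nval(s))
      up <- ag_resize(tape, h, ds[3], ds[4], model$config$upsample_mode)
      ag_concat(tape, list(s, up))
    }
    h <- fwd_stage(dec$block, tape, fusedin, training)
  }
  ag_sigmoid(tape, ag_conv(tape, h, model$head))
}

#' Predict lesion probability maps
#'
#' Runs the network in evaluation mode (batch-norm running statistics) on a
#' `(batch, channel, H, W)` array; `H` and `W` must be divisible by 8.
#'
#' @param object An `echoseg_model`.
#' @param x Input array.
#' @param ... Unused.
#' @return A `(batch, 1, H, W)` array of probabilities strictly in (0, 1).
#' @export
predict.echoseg_model <- function(object, x, ...) {
  fwd_model(object, NULL, x, training = FALSE)
}

#' Count trainable parameters
#'
#' @param model An `echoseg_model` (or any block/layer of one).
#' @return Exact number of trainable scalars (convolution and dense weights
#'   and biases, batch-norm scale and shift; running statistics excluded).
#' @export
count_parameters <- function(model) {
  n_params(model)
}

#' @export
print.echoseg_model <- function(x, ...) {
  cfg <- x$config
  cat("<echoseg_model>\n")
  cat("  stages:", paste(cfg$stage_widths, collapse = "-"),
      " in_channels:", cfg$in_channels, "\n")
  cat("  blocks: multi-receptive =", cfg$use_mrf,
      "| dual-scale =", cfg$use_dual_scale,
      "| SE-skip =", cfg$use_skip_se, "\n")
  if (cfg$use_mrf) cat("  dilations:", paste(cfg$dilations, collapse = ", "), "\n")
  cat("  trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
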