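# The three architectural blocks of the network:
#  * multi-receptive fusion block  — encoder stages 3-4: three dilated 3x3
#    branches with cross-branch coupling and interleaved spatial/channel
#    attention, concatenation-fused and refined by a final spatial attention;
#  * dual-scale attention block    — decoder stage processed in parallel at
#    native and doubled resolution with channel/spatial attention stages;
#  * SE skip fusion block          — skip connection refined by two cascaded
#    squeeze-and-excitation gates with residual shortcuts and dense fusion.

# ---- multi-receptive fusion -------------------------------------------------

new_mrf_block <- function(in_channels, out_channels, dilations = c(1L, 3L, 5L),
                          reduction = 8L, spatial_kernel = 7L,
                          fusion = c("concat", "sum")) {
  fusion <- match.arg(fusion)
  if (length(dilations) != 3L || any(diff(dilations) <= 0) || any(dilations < 1)) {
    stop("dilations must be a strictly increasing triple of positive integers",
         call. = FALSE)
  }
  W <- out_channels
  list(
    kind = "mrf_block",
    in_channels = in_channels, out_channels = out_channels,
    dilations = as.integer(dilations), fusion = fusion,
    entry = new_conv_bn_relu(in_channels, W, kernel = 1L),
    b1 = new_conv_bn_relu(W, W, dilation = dilations[1]),
    sa1 = new_spatial_attention(spatial_kernel),
    b2 = new_conv_bn_relu(W, W, dilation = dilations[2]),
    ca2 = new_channel_attention(W, reduction),
    b3 = new_conv_bn_relu(W, W, dilation = dilations[3]),
    sa3 = new_spatial_attention(spatial_kernel),
    fuse = if (fusion == "concat") new_conv_bn_relu(4L * W, W, kernel = 1L)
           else new_conv_bn_relu(W, W, kernel = 1L),
    sa_out = new_spatial_attention(spatial_kernel)
  )
}

fwd_mrf_block <- function(blk, tape, x, training) {
  if (dim(nval(x))[2] != blk$in_channels) {
    stop("multi-receptive block expected ", blk$in_channels, " channels, got ",
         dim(nval(x))[2], call. = FALSE)
  }
  main <- fwd_conv_bn_relu(blk$entry, tape, x, training)
  # branch 1: smallest receptive field, spatial attention
  y1 <- fwd_spatial_attention(blk$sa1, tape,
                              fwd_conv_bn_relu(blk$b1, tape, main, training))$output
  # branch 2 consumes main + branch-1 output (cross-branch coupling)
  x2 <- ag_add(tape, main, y1)
  y2 <- fwd_channel_attention(blk$ca2, tape,
                              fwd_conv_bn_relu(blk$b2, tape, x2, training))$output
  # branch 3 consumes main + both earlier branches
  x3 <- ag_add(tape, ag_add(tape, main, y1), y2)
  y3 <- fwd_spatial_attention(blk$sa3, tape,
                              fwd_conv_bn_relu(blk$b3, tape, x3, training))$output
  fused <- if (blk$fusion == "concat") {
    fwd_conv_bn_relu(blk$fuse, tape, ag_concat(tape, list(y1, y2, y3, main)), training)
  } else {
    s <- ag_add(tape, ag_add(tape, y1, y2), ag_add(tape, y3, main))
    fwd_conv_bn_relu(blk$fuse, tape, s, training)
  }
  fwd_spatial_attention(blk$sa_out, tape, fused)$output
}

#' Multi-receptive attention fusion over a feature map
#'
#' Encoder block enriching context at fixed resolution: a 1x1 convolution
#' unifies the width, three parallel 3x3 convolutions at increasing dilation
#' rates (default 1, 3, 5; effective kernel sides 3, 7, 11) are coupled so
#' each later branch also consumes the earlier branch outputs, spatial
#' attention refines branches 1 and 3 and channel attention branch 2, and the
#' three branches plus the main path are concatenated, fused by a 1x1
#' convolution and refined by a final spatial attention.
#'
#' @param x Rank-4 numeric array `(batch, channel, row, col)`.
#' @param out_channels Output width (default: the input width).
#' @param dilations Strictly increasing triple of dilation rates.
#' @param reduction Channel-attention bottleneck ratio.
#' @param spatial_kernel Odd spatial-attention filter width.
#' @param fusion `"concat"` (default) or `"sum"` final fusion.
#' @param module Optional module from a previous call (reuses parameters).
#' @return A list with `output` (same spatial extents as `x`) and `module`.
#' @export
multi_receptive_fusion <- function(x, out_channels = dim(x)[2],
                                   dilations = c(1L, 3L, 5L), reduction = 8L,
                                   spatial_kernel = 7L,
                                   fusion = c("concat", "sum"), module = NULL) {
  check_feature_map(x)
  if (is.null(module)) {
    module <- new_mrf_block(dim(x)[2], out_channels, dilations, reduction,
                            spatial_kernel, match.arg(fusion))
  }
  list(output = fwd_mrf_block(module, NULL, x, training = FALSE), module = module)
}

# ---- dual-scale attention ---------------------------------------------------

new_dual_scale_block <- function(in_channels, out_channels, reduction = 8L,
                                 spatial_kernel = 7L,
                                 upsample_mode = c("bilinear", "nearest")) {
  upsample_mode <- match.arg(upsample_mode)
  list(
    kind = "dual_scale_block",
    in_channels = in_channels, out_channels = out_channels,
    upsample_mode = upsample_mode,
    conv_a = new_conv_bn_relu(in_channels, out_channels),
    ca_a = new_channel_attention(out_channels, reduction),
    conv_b = new_conv_bn_relu(in_channels, out_channels),
    ca_b = new_channel_attention(out_channels, reduction),
    conv1 = new_conv_bn_relu(out_channels, out_channels),
    ca1 = new_channel_attention(out_channels, reduction),
    conv2 = new_conv_bn_relu(out_channels, out_channels),
    sa2 = new_spatial_attention(spatial_kernel)
  )
}

fwd_dual_scale_block <- function(blk, tape, x, training) {
  d <- dim(nval(x))
  if (d[3] < 2 || d[4] < 2) {
    stop("dual-scale block needs spatial extents >= 2, got ", d[3], "x", d[4],
         call. = FALSE)
  }
  # scale A: native resolution; pre-attention map kept as a residual
  # (f + f*w, fused as a gated shortcut)
  fa <- fwd_conv_bn_relu(blk$conv_a, tape, x, training)
  fa2 <- ag_gate_residual(tape, fa, fwd_channel_attention(blk$ca_a, tape, fa)$weights)
  # scale B: doubled resolution for broader context, folded back by box
  # averaging to the exact native extents (handles odd sizes)
  xb <- ag_resize(tape, x, 2L * d[3], 2L * d[4], blk$upsample_mode)
  fb <- fwd_conv_bn_relu(blk$conv_b, tape, xb, training)
  fb2 <- ag_gate_residual(tape, fb, fwd_channel_attention(blk$ca_b, tape, fb)$weights)
  fbd <- ag_resize(tape, fb2, d[3], d[4], "area")
  fused <- ag_add(tape, fa2, fbd)
  t1 <- fwd_channel_attention(blk$ca1, tape,
                              fwd_conv_bn_relu(blk$conv1, tape, fused, training))$output
  fwd_spatial_attention(blk$sa2, tape,
                        fwd_conv_bn_relu(blk$conv2, tape, t1, training))$output
}

#' Dual-scale attention enhancement of a decoder feature map
#'
#' Processes the input in parallel at native and doubled resolution: each
#' scale passes a 3x3 convolution and channel attention with an additive
#' shortcut from the pre-attention map, the upsampled branch is box-averaged
#' back to the native extents and summed with the native branch, and the
#' fusion passes two further convolution+attention stages (channel attention,
#' then spatial attention).
#'
#' @inheritParams multi_receptive_fusion
#' @param upsample_mode `"bilinear"` (default) or `"nearest"` for the 2x
#'   branch.
#' @return A list with `output` (native extents, `out_channels` wide) and
#'   `module`.
#' @export
dual_scale_enhance <- function(x, out_channels = dim(x)[2], reduction = 8L,
                               spatial_kernel = 7L,
                               upsample_mode = c("bilinear", "nearest"),
                               module = NULL) {
  check_feature_map(x)
  if (is.null(module)) {
    module <- new_dual_scale_block(dim(x)[2], out_channels, reduction,
                                   spatial_kernel, match.arg(upsample_mode))
  }
  list(output = fwd_dual_scale_block(module, NULL, x, training = FALSE),
       module = module)
}

# ---- SE skip fusion ---------------------------------------------------------

new_skip_se_block <- function(enc_channels, dec_channels, out_channels,
                              reduction = 8L,
                              path_mode = c("dual", "input1_only", "input2_only"),
                              use_residual = TRUE) {
  path_mode <- match.arg(path_mode)
  base_channels <- switch(path_mode,
    dual = enc_channels + dec_channels,
    input1_only = enc_channels,
    input2_only = dec_channels
  )
  list(
    kind = "skip_se_block",
    enc_channels = enc_channels, dec_channels = dec_channels,
    out_channels = out_channels, path_mode = path_mode,
    base_channels = base_channels, use_residual = use_residual,
    conv_enc = new_conv_bn_relu(enc_channels, enc_channels),
    se1 = new_se_block(base_channels, reduction),
    se2 = new_se_block(base_channels, reduction),
    conv_c = new_conv_bn_relu(base_channels, base_channels),
    fuse = new_conv_bn_relu(3L * base_channels, out_channels, kernel = 1L)
  )
}

fwd_skip_se_block <- function(blk, tape, input1, input2, training,
                              internals = FALSE) {
  d1 <- dim(nval(input1))
  d2 <- dim(nval(input2))
  if (abs(d2[3] * 2 - d1[3]) > 2 || abs(d2[4] * 2 - d1[4]) > 2) {
    stop("decoder input extents (", d2[3], "x", d2[4], ") are not half the ",
         "skip extents (", d1[3], "x", d1[4], ")", call. = FALSE)
  }
  up2 <- ag_resize(tape, input2, d1[3], d1[4], "bilinear")
  a1 <- fwd_conv_bn_relu(blk$conv_enc, tape, input1, training)
  base <- switch(blk$path_mode,
    dual = ag_concat(tape, list(a1, up2)),
    input1_only = a1,
    input2_only = up2
  )
  gate <- function(se, h) {
    w <- fwd_se_block(se, tape, h)$weights
    if (blk$use_residual) ag_gate_residual(tape, h, w) else ag_scale_channel(tape, h, w)
  }
  e1 <- gate(blk$se1, base)
  e2 <- gate(blk$se2, e1)
  cc <- fwd_conv_bn_relu(blk$conv_c, tape, e2, training)
  out <- fwd_conv_bn_relu(blk$fuse, tape, ag_concat(tape, list(e1, e2, cc)), training)
  if (internals) list(output = out, base = base, enhanced1 = e1, enhanced2 = e2) else out
}

#' SE-enhanced fusion of a skip connection with decoder features
#'
#' Aligns the deeper decoder stream (`input2`, at half resolution) to the
#' encoder skip stream (`input1`) by bilinear upsampling, unifies the skip
#' stream with a 3x3 convolution, concatenates the two, and refines the base
#' features with two cascaded squeeze-and-excitation gates, each wrapped in an
#' additive residual shortcut. A 3x3 convolution extracts local features from
#' the second enhancement and the three maps are densely fused by a 1x1
#' convolution. Single-path modes keep the cascade but feed it only one
#' aligned stream.
#'
#' @param input1 Encoder skip features `(batch, channel, H, W)`.
#' @param input2 Decoder features `(batch, channel, H/2, W/2)`.
#' @param out_channels Output width (default: the skip width).
#' @param reduction SE bottleneck ratio.
#' @param path_mode `"dual"` (default), `"input1_only"` or `"input2_only"`.
#' @param module Optional module from a previous call.
#' @return A list with `output` (spatial extents of `input1`) and `module`.
#' @export
skip_se_fusion <- function(input1, input2, out_channels = dim(input1)[2],
                           reduction = 8L,
                           path_mode = c("dual", "input1_only", "input2_only"),
                           module = NULL) {
  check_feature_map(input1)
  check_feature_map(input2)
  if (is.null(module)) {
    module <- new_skip_se_block(dim(input1)[2], dim(input2)[2], out_channels,
                                reduction, match.arg(path_mode))
  }
  list(output = fwd_skip_se_block(module, NULL, input1, input2, training = FALSE),
       module = module)
}
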