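# Attention primitives: spatial attention and channel attention in the CBAM
# lineage, plus the squeeze-and-excitation (SE) gate used on skip connections.
# Each has a module constructor (used inside network blocks) and an exported
# functional form operating on plain (batch, channel, row, col) arrays.

new_spatial_attention <- function(kernel = 7L) {
  if (kernel %% 2 == 0 || kernel < 3) {
    stop("spatial attention kernel must be odd and >= 3, got ", kernel, call. = FALSE)
  }
  list(kind = "spatial_attention", kernel = as.integer(kernel),
       conv = new_conv2d(2L, 1L, kernel = kernel))
}

# Returns list(weights, output): weights (N, 1, H, W) in (0, 1), output = x
# gated per pixel. The descriptor is the channel-wise mean map stacked with
# the channel-wise max map, convolved to a single channel, then sigmoid.
fwd_spatial_attention <- function(mod, tape, x) {
  s <- ag_chan_mm(tape, x)
  w <- ag_sigmoid(tape, ag_conv(tape, s, mod$conv))
  list(weights = w, output = ag_scale_spatial(tape, x, w))
}

hidden_width <- function(channels, reduction) max(1L, as.integer(channels %/% reduction))

new_channel_attention <- function(channels, reduction = 8L) {
  if (reduction <= 0) stop("reduction must be a positive integer", call. = FALSE)
  hid <- hidden_width(channels, reduction)
  # one bottleneck shared by the average-pool and max-pool descriptors
  list(kind = "channel_attention", channels = channels,
       fc1 = new_dense(channels, hid), fc2 = new_dense(hid, channels))
}

fwd_channel_attention <- function(mod, tape, x) {
  squeeze <- function(desc) {
    ag_dense(tape, ag_relu(tape, ag_dense(tape, desc, mod$fc1)), mod$fc2)
  }
  a <- squeeze(ag_gap(tape, x))
  m <- squeeze(ag_gmp(tape, x))
  w <- ag_sigmoid(tape, ag_as_gate(tape, ag_add(tape, a, m)))
  list(weights = w, output = ag_scale_channel(tape, x, w))
}

new_se_block <- function(channels, reduction = 8L) {
  if (reduction <= 0) stop("reduction must be a positive integer", call. = FALSE)
  hid <- hidden_width(channels, reduction)
  list(kind = "se_block", channels = channels,
       fc1 = new_dense(channels, hid), fc2 = new_dense(hid, channels))
}

# SE differs from channel attention exactly by the absence of the max-pool
# descriptor path: squeeze = global average pool only.
fwd_se_block <- function(mod, tape, x) {
  z <- ag_dense(tape, ag_relu(tape, ag_dense(tape, ag_gap(tape, x), mod$fc1)), mod$fc2)
  w <- ag_sigmoid(tape, ag_as_gate(tape, z))
  list(weights = w, output = ag_scale_channel(tape, x, w))
}

check_feature_map <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop("feature map must be a rank-4 array (batch, channel, row, col)", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("feature map contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Spatial attention over a feature map
#'
#' Gates each pixel of a `(batch, channel, row, col)` activation array by a
#' weight in (0, 1) derived from its channel-wise mean and max descriptors:
#' the two maps are stacked, convolved with a single `kernel x kernel` filter,
#' and passed through a sigmoid. Freshly initialised filter parameters are
#' drawn from the current RNG unless a `module` built by an earlier call is
#' supplied.
#'
#' @param x Rank-4 numeric array `(batch, channel, row, col)`.
#' @param kernel Odd integer filter width (default 7).
#' @param module Optional module returned by a previous call (reuses weights).
#' @return A list with `weights` (`(batch, 1, row, col)` array in (0, 1)),
#'   `output` (gated copy of `x`) and `module` (the parameter container).
#' @examples
#' x <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
#' sa <- spatial_attention(x)
#' dim(sa$weights)
#' @export
spatial_attention <- function(x, kernel = 7L, module = NULL) {
  check_feature_map(x)
  if (is.null(module)) module <- new_spatial_attention(kernel)
  r <- fwd_spatial_attention(module, NULL, x)
  list(weights = r$weights, output = r$output, module = module)
}

#' Channel attention over a feature map
#'
#' Re-weights channels using global average- and max-pooled descriptors passed
#' through a shared two-layer bottleneck (`channels -> channels/reduction ->
#' channels`, rectifier between), summed and squashed by a sigmoid.
#'
#' @inheritParams spatial_attention
#' @param reduction Positive integer bottleneck ratio (default 8); the hidden
#'   width is clamped to at least 1.
#' @return A list with `weights` (`(batch, channel, 1, 1)` array in (0, 1)),
#'   `output` and `module`.
#' @export
channel_attention <- function(x, reduction = 8L, module = NULL) {
  check_feature_map(x)
  if (is.null(module)) module <- new_channel_attention(dim(x)[2], reduction)
  r <- fwd_channel_attention(module, NULL, x)
  list(weights = r$weights, output = r$output, module = module)
}

#' Squeeze-and-excitation gate over a feature map
#'
#' Classic SE block: squeeze is global average pooling only; excitation is a
#' two-layer fully-connected bottleneck followed by a sigmoid, and the
#' resulting per-channel weights multiply the input channel by channel.
#'
#' @inheritParams channel_attention
#' @return A list with `weights`, `output` and `module`, as
#'   [channel_attention()].
#' @export
se_block <- function(x, reduction = 8L, module = NULL) {
  check_feature_map(x)
  if (is.null(module)) module <- new_se_block(dim(x)[2], reduction)
  r <- fwd_se_block(module, NULL, x)
  list(weights = r$weights, output = r$output, module = module)
}
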