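# Trainable layer containers. Layers are environments so running statistics
# (batch norm) update in place; parameters are `echoseg_param` environments
# discovered recursively by collect_params().

new_conv2d <- function(in_channels, out_channels, kernel = 3L, dilation = 1L,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  stopifnot(kernel %% 2 == 1)
  n <- kernel * kernel * in_channels
  W <- if (init == "he") {
    array(stats::rnorm(n * out_channels, sd = sqrt(2 / n)),
          c(kernel, kernel, in_channels, out_channels))
  } else {
    array(0, c(kernel, kernel, in_channels, out_channels))
  }
  l <- new.env(parent = emptyenv())
  l$kind <- "conv2d"
  l$W <- new_param(W)
  l$b <- new_param(numeric(out_channels))
  l$dilation <- as.integer(dilation)
  class(l) <- "echoseg_layer"
  l
}

new_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$kind <- "batchnorm"
  l$gamma <- new_param(rep(1, channels))
  l$beta <- new_param(numeric(channels))
  l$running_mean <- numeric(channels)
  l$running_var <- rep(1, channels)
  l$momentum <- momentum
  l$eps <- eps
  class(l) <- "echoseg_layer"
  l
}

new_dense <- function(in_features, out_features, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "he") {
    matrix(stats::rnorm(out_features * in_features, sd = sqrt(2 / in_features)),
           out_features, in_features)
  } else {
    matrix(0, out_features, in_features)
  }
  l <- new.env(parent = emptyenv())
  l$kind <- "dense"
  l$W <- new_param(W)
  l$b <- new_param(numeric(out_features))
  class(l) <- "echoseg_layer"
  l
}

# conv -> batch norm -> rectifier, the default unit everywhere in the network.
new_conv_bn_relu <- function(in_channels, out_channels, kernel = 3L, dilation = 1L) {
  list(
    kind = "conv_bn_relu",
    conv = new_conv2d(in_channels, out_channels, kernel, dilation),
    bn = new_batchnorm(out_channels)
  )
}

fwd_conv_bn_relu <- function(blk, tape, x, training) {
  ag_cbr(tape, x, blk, training)
}

# Two stacked 3x3 conv-bn-relu units (the plain encoder/decoder stage).
new_double_conv <- function(in_channels, out_channels) {
  list(
    kind = "double_conv",
    c1 = new_conv_bn_relu(in_channels, out_channels),
    c2 = new_conv_bn_relu(out_channels, out_channels)
  )
}

fwd_double_conv <- function(blk, tape, x, training) {
  fwd_conv_bn_relu(blk$c2, tape, fwd_conv_bn_relu(blk$c1, tape, x, training), training)
}

# Recursively harvest every parameter container in a (nested) module.
collect_params <- function(x) {
  if (is_param(x)) return(list(x))
  if (inherits(x, "echoseg_layer")) {
    out <- list()
    for (nm in ls(x)) if (is_param(x[[nm]])) out[[length(out) + 1L]] <- x[[nm]]
    return(out)
  }
  if (is.list(x)) {
    return(do.call(c, c(lapply(x, collect_params), list(list()))))
  }
  list()
}

n_params <- function(x) sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(NULL)
}

# Set every parameter of a module to zero (test/diagnostic hook: with all
# attention parameters zero, every sigmoid gate outputs exactly 0.5).
zero_params <- function(x) {
  for (p in collect_params(x)) p$value[] <- 0
  invisible(x)
}

# Deep-copy parameter values (checkpointing).
snapshot_params <- function(x) lapply(collect_params(x), function(p) p$value)

restore_params <- function(x, snap) {
  ps <- collect_params(x)
  stopifnot(length(ps) == length(snap))
  for (i in seq_along(ps)) ps[[i]]$value <- snap[[i]]
  invisible(x)
}

# Batch-norm running statistics, kept separately from trainable parameters.
collect_bn_layers <- function(x) {
  if (inherits(x, "echoseg_layer")) {
    return(if (identical(x$kind, "batchnorm")) list(x) else list())
  }
  if (is.list(x)) {
    return(do.call(c, c(lapply(x, collect_bn_layers), list(list()))))
  }
  list()
}

snapshot_bn_stats <- function(x) {
  lapply(collect_bn_layers(x), function(l) list(m = l$running_mean, v = l$running_var))
}

restore_bn_stats <- function(x, snap) {
  ls <- collect_bn_layers(x)
  stopifnot(length(ls) == length(snap))
  for (i in seq_along(ls)) {
    ls[[i]]$running_mean <- snap[[i]]$m
    ls[[i]]$running_var <- snap[[i]]$v
  }
  invisible(x)
}
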