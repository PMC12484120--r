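# Reverse-mode automatic differentiation over rank-4 activation arrays.
#
# All tensors use the contract layout (batch, channel, row, col). A "tape" is
# an environment collecting operation nodes in execution order; calling
# ag_backward() sweeps the tape in reverse and accumulates gradients into the
# trainable parameter containers. Every ag_* op also runs with tape = NULL,
# in which case it takes and returns plain arrays (pure inference, no graph).

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- array(0, dim = if (is.null(dim(value))) length(value) else dim(value))
  class(p) <- "echoseg_param"
  p
}

is_param <- function(x) inherits(x, "echoseg_param")

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "echoseg_tape"
  t
}

is_node <- function(x) inherits(x, "echoseg_node")

# Value of a node or a plain array.
nval <- function(x) if (is_node(x)) x$value else x

ag_push <- function(tape, value, parents = list(), backward = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  nd$grad <- NULL
  needs <- !is.null(param)
  if (!needs) {
    for (p in parents) {
      if (is_node(p) && isTRUE(p$needs)) { needs <- TRUE; break }
    }
  }
  nd$needs <- needs
  class(nd) <- "echoseg_node"
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

# Emit a result: raw value when untaped, a graph node otherwise. Parents may
# mix nodes and plain arrays; positions must match the backward's gradient
# list (non-node parents are skipped during accumulation).
emit <- function(tape, value, parents = list(), backward = NULL) {
  if (is.null(tape)) return(value)
  ag_push(tape, value, parents = parents, backward = backward)
}

ag_const <- function(tape, value) {
  if (is.null(tape)) return(value)
  ag_push(tape, value)
}

ag_param_node <- function(tape, param) {
  if (is.null(tape)) return(param$value)
  ag_push(tape, param$value, param = param)
}

accumulate_grad <- function(node, g) {
  if (!is_node(node) || is.null(g) || !isTRUE(node$needs)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse sweep from `loss` (a scalar-valued node). Gradients land in
# node$grad and, for parameter leaves, in param$grad (accumulated).
ag_backward <- function(tape, loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backward)) {
      gs <- nd$backward(nd$grad)
      ps <- nd$parents
      for (j in seq_along(ps)) accumulate_grad(ps[[j]], gs[[j]])
    }
    if (!is.null(nd$param)) {
      nd$param$grad <- nd$param$grad + nd$grad
    }
    # free memory held by interior nodes as soon as they are consumed
    nd$grad <- NULL
  }
  invisible(NULL)
}

# ---- shape helpers ---------------------------------------------------------

dim4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a rank-4 array", call. = FALSE)
  d
}

# Per-channel sum of a (N, C, H, W) array -> length-C vector.
chan_sum <- function(x) {
  d <- dim4(x)
  rowSums(matrix(colSums(x, dims = 1L), nrow = d[2]))
}

# Broadcast a length-C vector over (N, C, H, W).
bcast_c <- function(v, d) rep(v, each = d[1]) # recycled over H, W by arithmetic

# Broadcast a (N, 1, H, W) array over channels.
bcast_s <- function(w, C) {
  d <- dim(w)
  w[, rep(1L, C), , , drop = FALSE]
}

# ---- elementwise -----------------------------------------------------------

ag_relu <- function(tape, x) {
  xv <- nval(x)
  y <- .relu_fw(xv)
  emit(tape, y, list(x), function(g) list(.relu_bw(g, xv)))
}

ag_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-nval(x)))
  emit(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(tape, a, b) {
  av <- nval(a); bv <- nval(b)
  stopifnot(identical(dim(av), dim(bv)))
  emit(tape, av + bv, list(a, b), function(g) list(g, g))
}

ag_scale_const <- function(tape, x, k) {
  emit(tape, k * nval(x), list(x), function(g) list(k * g))
}

# y = x * w with w of shape (N, C, 1, 1): per-channel gating.
ag_scale_channel <- function(tape, x, w) {
  xv <- nval(x); wv <- nval(w)
  y <- .nc_scale(xv, wv)
  emit(tape, y, list(x, w), function(g) {
    list(.nc_scale(g, wv), .nc_dot(g, xv))
  })
}

# y = x * w with w of shape (N, 1, H, W): per-pixel gating.
ag_scale_spatial <- function(tape, x, w) {
  xv <- nval(x); wv <- nval(w)
  d <- dim4(xv)
  y <- .sscale_fw(xv, wv)
  emit(tape, y, list(x, w), function(g) {
    list(.sscale_fw(g, wv), .sscale_gw(g, xv))
  })
}

# Gated residual y = x * w + x = x * (1 + w) with a per-(batch, channel)
# gate (the SE-with-shortcut pattern), fused into one pass.
ag_gate_residual <- function(tape, x, w) {
  xv <- nval(x); wv <- nval(w)
  w1 <- wv + 1
  y <- .nc_scale(xv, w1)
  emit(tape, y, list(x, w), function(g) {
    list(.nc_scale(g, w1), .nc_dot(g, xv))
  })
}

# Concatenate along the channel axis.
ag_concat <- function(tape, xs) {
  vals <- lapply(xs, nval)
  cs <- vapply(vals, function(v) dim4(v)[2], integer(1))
  y <- .concat_c(vals)
  emit(tape, y, xs, function(g) .split_c(g, cs))
}

# ---- convolution / batch norm / dense --------------------------------------

ag_conv <- function(tape, x, layer, training = TRUE) {
  xv <- nval(x)
  y <- .conv2d_fw(xv, layer$W$value, layer$b$value, layer$dilation)
  if (is.null(tape)) return(y)
  wn <- ag_param_node(tape, layer$W)
  bn <- ag_param_node(tape, layer$b)
  dil <- layer$dilation
  wv <- layer$W$value
  need_gx <- is_node(x) && isTRUE(x$needs) # skip image gradient at the stem
  ag_push(tape, y, parents = list(x, wn, bn), backward = function(g) {
    r <- .conv2d_bw(xv, wv, g, dil, need_gx)
    list(r$gx, r$gw, r$gb)
  })
}

# Batch normalization over (batch, row, col) per channel. Training mode uses
# batch statistics and updates the layer's running estimates in place; eval
# mode uses the running estimates (identity transform at initialization).
ag_bn <- function(tape, x, layer, training = TRUE) {
  xv <- nval(x)
  d <- dim4(xv)
  M <- d[1] * d[3] * d[4]
  eps <- layer$eps
  gam <- layer$gamma$value
  bet <- layer$beta$value
  if (training) {
    mu <- .chan_sum(xv) / M
    va <- .chan_dot(xv, xv) / M - mu^2
    va <- pmax(va, 0)
    inv <- 1 / sqrt(va + eps)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * va
  } else {
    mu <- layer$running_mean
    inv <- 1 / sqrt(layer$running_var + eps)
  }
  xhat <- .chan_affine(xv, inv, -mu * inv)
  y <- .chan_affine(xhat, gam, bet)
  if (is.null(tape)) return(y)
  gn <- ag_param_node(tape, layer$gamma)
  bn <- ag_param_node(tape, layer$beta)
  ag_push(tape, y, parents = list(x, gn, bn), backward = function(g) {
    dbeta <- .chan_sum(g)
    dgamma <- .chan_dot(g, xhat)
    if (training) {
      dx <- .chan_affine2(g, xhat, gam * inv, -gam * inv * dgamma / M,
                          -gam * inv * dbeta / M)
    } else {
      dx <- .chan_affine(g, gam * inv, numeric(length(gam)))
    }
    list(dx, dgamma, dbeta)
  })
}

# Fused convolution -> batch norm -> rectifier unit (the network's standard
# stage). One compiled epilogue computes the batch statistics, normalized
# activations and rectified output in two array passes.
ag_cbr <- function(tape, x, blk, training = TRUE) {
  conv <- blk$conv
  bn <- blk$bn
  xv <- nval(x)
  z <- .conv2d_fw(xv, conv$W$value, conv$b$value, conv$dilation)
  r <- .bnrelu_fw(z, bn$gamma$value, bn$beta$value, bn$eps, training,
                  bn$running_mean, bn$running_var)
  if (training) {
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * r$mu
    bn$running_var <- (1 - bn$momentum) * bn$running_var + bn$momentum * r$var
  }
  if (is.null(tape)) return(r$y)
  wn <- ag_param_node(tape, conv$W)
  bnn <- ag_param_node(tape, conv$b)
  gn <- ag_param_node(tape, bn$gamma)
  ben <- ag_param_node(tape, bn$beta)
  wv <- conv$W$value
  gam <- bn$gamma$value
  inv <- r$inv
  yv <- r$y
  xhat <- r$xhat
  dil <- conv$dilation
  need_gx <- is_node(x) && isTRUE(x$needs)
  ag_push(tape, yv, parents = list(x, wn, bnn, gn, ben), backward = function(g) {
    rb <- .bnrelu_bw(g, yv, xhat, gam, inv, training)
    cb <- .conv2d_bw(xv, wv, rb$dz, dil, need_gx)
    list(cb$gx, cb$gw, cb$gb, rb$dgamma, rb$dbeta)
  })
}

# Fully-connected layer on (batch, features) matrices.
ag_dense <- function(tape, x, layer) {
  xv <- nval(x)
  Wv <- layer$W$value # (out, in)
  y <- tcrossprod(xv, Wv)
  y <- y + matrix(layer$b$value, nrow(y), ncol(y), byrow = TRUE)
  if (is.null(tape)) return(y)
  wn <- ag_param_node(tape, layer$W)
  bn <- ag_param_node(tape, layer$b)
  ag_push(tape, y, parents = list(x, wn, bn), backward = function(g) {
    list(g %*% Wv, crossprod(g, xv), colSums(g))
  })
}

# ---- pooling / resizing ----------------------------------------------------

ag_maxpool2 <- function(tape, x) {
  xv <- nval(x)
  d <- dim4(xv)
  stopifnot(d[3] %% 2 == 0, d[4] %% 2 == 0)
  ho <- seq(1L, d[3], 2L); he <- ho + 1L
  wo <- seq(1L, d[4], 2L); we <- wo + 1L
  subs <- list(
    xv[, , ho, wo, drop = FALSE], xv[, , he, wo, drop = FALSE],
    xv[, , ho, we, drop = FALSE], xv[, , he, we, drop = FALSE]
  )
  best <- subs[[1]]
  idx <- array(1L, dim(best))
  for (k in 2:4) {
    m <- subs[[k]] > best
    best[m] <- subs[[k]][m]
    idx[m] <- k
  }
  rows <- list(ho, he, ho, he)
  cols <- list(wo, wo, we, we)
  emit(tape, best, list(x), function(g) {
    gx <- array(0, d)
    for (k in 1:4) {
      gx[, , rows[[k]], cols[[k]]] <- gx[, , rows[[k]], cols[[k]], drop = FALSE] + g * (idx == k)
    }
    list(gx)
  })
}

# Interpolation matrix (n_out x n_in) along one axis.
# bilinear: half-pixel-centre linear interpolation; nearest: index snapping;
# area: exact box averaging (the 2x case is 0.5/0.5 average pooling).
resize_matrix <- function(n_in, n_out, mode = c("bilinear", "nearest", "area")) {
  mode <- match.arg(mode)
  A <- matrix(0, n_out, n_in)
  if (mode == "nearest") {
    src <- pmin(floor((seq_len(n_out) - 1L) * n_in / n_out), n_in - 1L)
    A[cbind(seq_len(n_out), src + 1L)] <- 1
  } else if (mode == "bilinear") {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    s <- pmin(pmax(s, 0), n_in - 1)
    i0 <- floor(s)
    f <- s - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    for (i in seq_len(n_out)) {
      A[i, i0[i] + 1L] <- A[i, i0[i] + 1L] + (1 - f[i])
      A[i, i1[i] + 1L] <- A[i, i1[i] + 1L] + f[i]
    }
  } else {
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * n_in / n_out
      hi <- i * n_in / n_out
      for (j in seq.int(floor(lo), ceiling(hi) - 1)) {
        ov <- min(hi, j + 1) - max(lo, j)
        if (ov > 0) A[i, j + 1L] <- ov / (hi - lo)
      }
    }
  }
  A
}

# Apply separable row/col resampling matrices A (H'xH), B (W'xW) to (N,C,H,W).
apply_resize_hw <- function(x, A, B) {
  .resize_hw(x, A, B)
}

ag_resize <- function(tape, x, out_h, out_w, mode = "bilinear") {
  xv <- nval(x)
  d <- dim4(xv)
  # fast paths for the exact-2x factors the network uses everywhere
  if (out_h == 2L * d[3] && out_w == 2L * d[4]) {
    if (mode == "nearest") {
      return(emit(tape, .up2_nearest(xv), list(x),
                  function(g) list(4 * .down2_area(g))))
    }
    if (mode == "bilinear") {
      y <- .up2_bilinear(xv)
      return(emit(tape, y, list(x), function(g) {
        A <- t(resize_matrix(d[3], out_h, "bilinear"))
        B <- t(resize_matrix(d[4], out_w, "bilinear"))
        list(apply_resize_hw(g, A, B))
      }))
    }
  }
  if (mode == "area" && d[3] == 2L * out_h && d[4] == 2L * out_w) {
    return(emit(tape, .down2_area(xv), list(x),
                function(g) list(.up2_nearest(g) / 4)))
  }
  A <- resize_matrix(d[3], out_h, mode)
  B <- resize_matrix(d[4], out_w, mode)
  y <- apply_resize_hw(xv, A, B)
  emit(tape, y, list(x), function(g) list(apply_resize_hw(g, t(A), t(B))))
}

# Global average pool: (N, C, H, W) -> (N, C) descriptor matrix.
ag_gap <- function(tape, x) {
  xv <- nval(x)
  d <- dim4(xv)
  y <- .gap_fw(xv)
  emit(tape, y, list(x), function(g) {
    gx <- matrix(as.vector(g) / (d[3] * d[4]), d[1] * d[2], d[3] * d[4])
    dim(gx) <- d
    list(gx)
  })
}

# Global max pool: (N, C, H, W) -> (N, C).
ag_gmp <- function(tape, x) {
  xv <- nval(x)
  d <- dim4(xv)
  r <- .gmp_fw(xv)
  j <- as.vector(r$argmax) # 1-based flat pixel index per (n, c)
  y <- r$value
  emit(tape, y, list(x), function(g) {
    gx <- matrix(0, d[1] * d[2], d[3] * d[4])
    gx[cbind(seq_len(nrow(gx)), j)] <- as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

# Stacked channel-wise mean and max maps: (N, C, H, W) -> (N, 2, H, W),
# channel 1 = mean over channels, channel 2 = max (the spatial-attention
# descriptor pair, fused into one op).
ag_chan_mm <- function(tape, x) {
  xv <- nval(x)
  d <- dim4(xv)
  r <- .cmaps_fw(xv)
  y <- array(0, c(d[1], 2L, d[3], d[4]))
  y[, 1L, , ] <- r$mean
  y[, 2L, , ] <- r$max
  emit(tape, y, list(x), function(g) {
    gmean <- g[, 1L, , , drop = FALSE]
    gmax <- g[, 2L, , , drop = FALSE]
    list(.cmaps_bw(gmean, gmax, r$argmax, d[2]))
  })
}

# Reshape a (N, C) descriptor to channel-gate shape (N, C, 1, 1).
ag_as_gate <- function(tape, x) {
  xv <- nval(x)
  y <- array(xv, c(nrow(xv), ncol(xv), 1L, 1L))
  emit(tape, y, list(x), function(g) list(matrix(g, dim(y)[1], dim(y)[2])))
}

# Soft Dice loss, mean over the batch; eps guards empty masks.
ag_dice_loss <- function(tape, p, y, eps = 1e-9) {
  pv <- nval(p)
  N <- dim(pv)[1]
  pm <- matrix(pv, nrow = N)
  ym <- matrix(y, nrow = N)
  S <- rowSums(pm * ym)
  D <- rowSums(pm) + rowSums(ym)
  li <- 1 - (2 * S + eps) / (D + eps)
  loss <- mean(li)
  emit(tape, loss, list(p), function(g) {
    gm <- -(2 * ym * (D + eps) - (2 * S + eps)) / (D + eps)^2 / N * g
    dim(gm) <- dim(pv)
    list(gm)
  })
}
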