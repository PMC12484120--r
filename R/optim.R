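# First-order optimizers over echoseg_param containers. State lives beside
# each parameter in the optimizer environment, keyed by position.

#' Optimizer constructor
#'
#' @param name One of `"adam"`, `"adagrad"`, `"adamax"`, `"rmsprop"`, `"sgd"`.
#' @param params List of parameter containers (from a built model).
#' @param lr Learning rate (default 0.001).
#' @return An optimizer object for [optimizer_step()].
#' @export
new_optimizer <- function(name = c("adam", "adagrad", "adamax", "rmsprop", "sgd"),
                          params, lr = 0.001) {
  name <- match.arg(name)
  opt <- new.env(parent = emptyenv())
  opt$name <- name
  opt$params <- params
  opt$lr <- lr
  opt$t <- 0L
  opt$beta1 <- 0.9
  opt$beta2 <- 0.999
  opt$rho <- 0.9
  opt$eps <- 1e-8
  zero <- function(p) array(0, dim = if (is.null(dim(p$value))) length(p$value) else dim(p$value))
  if (name %in% c("adam", "adamax")) {
    opt$m <- lapply(params, zero)
    opt$v <- lapply(params, zero)
  } else if (name %in% c("adagrad", "rmsprop")) {
    opt$v <- lapply(params, zero)
  }
  class(opt) <- "echoseg_optimizer"
  opt
}

#' Apply one optimization step and clear gradients
#'
#' @param opt An optimizer from [new_optimizer()].
#' @return The optimizer, invisibly.
#' @export
optimizer_step <- function(opt) {
  opt$t <- opt$t + 1L
  lr <- opt$lr
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    upd <- switch(opt$name,
      sgd = lr * g,
      adagrad = {
        opt$v[[i]] <- opt$v[[i]] + g^2
        lr * g / (sqrt(opt$v[[i]]) + opt$eps)
      },
      rmsprop = {
        opt$v[[i]] <- opt$rho * opt$v[[i]] + (1 - opt$rho) * g^2
        lr * g / (sqrt(opt$v[[i]]) + opt$eps)
      },
      adam = {
        opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
        opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
        mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
        vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
        lr * mhat / (sqrt(vhat) + opt$eps)
      },
      adamax = {
        opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
        opt$v[[i]] <- pmax(opt$beta2 * opt$v[[i]], abs(g))
        lr / (1 - opt$beta1^opt$t) * opt$m[[i]] / (opt$v[[i]] + opt$eps)
      }
    )
    p$value <- p$value - upd
    p$grad[] <- 0
  }
  invisible(opt)
}
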