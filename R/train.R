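# Training loop: Dice-loss optimization with per-epoch curve logging,
# best-validation checkpointing and deterministic seeding.

#' Training configuration
#'
#' Defaults follow the reference regime: Adam, learning rate 0.001, 200
#' epochs, batch size 16, no augmentation, no early stopping.
#'
#' @param optimizer One of `"adam"`, `"adagrad"`, `"adamax"`, `"rmsprop"`,
#'   `"sgd"`.
#' @param learning_rate Positive learning rate.
#' @param epochs Number of epochs.
#' @param batch_size Batch size.
#' @param seed Seed controlling weight initialization (via [fit_segmentation()])
#'   and shuffling.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping, or `NULL` (default) to always run all epochs.
#' @param threshold Binarization threshold used for logged pixel accuracy.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.001,
                         epochs = 200L, batch_size = 16L, seed = 1L,
                         early_stop_patience = NULL, threshold = 0.5) {
  optimizer <- match.arg(optimizer, c("adam", "adagrad", "adamax", "rmsprop", "sgd"))
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), early_stop_patience = early_stop_patience,
         threshold = threshold),
    class = "train_config"
  )
}

pixel_accuracy <- function(pred, y, threshold = 0.5) {
  mean((pred > threshold) == (y > 0.5))
}

# Forward a (possibly large) array in evaluation mode, batching for memory.
predict_batched <- function(model, x, batch_size = 16L) {
  n <- dim(x)[1]
  out <- array(0, c(n, 1L, dim(x)[3], dim(x)[4]))
  for (ix in make_batches(n, batch_size)) {
    out[ix, , , ] <- fwd_model(model, NULL, x[ix, , , , drop = FALSE], training = FALSE)
  }
  out
}

#' Train a segmentation model on in-memory arrays
#'
#' Optimizes the soft Dice loss. One step per batch; training order is
#' reshuffled each epoch from `config$seed`. Logs per-epoch training and
#' validation loss and pixel accuracy, and snapshots the parameters with the
#' best validation loss. Aborts with a diagnostic if the loss turns
#' non-finite.
#'
#' @param model An `echoseg_model` (modified in place; also returned).
#' @param data Named list with `train` and `val` elements, each
#'   `list(x, y)` of `(n, C, H, W)` inputs and `(n, 1, H, W)` masks, e.g.
#'   from [load_split()] or [samples_to_arrays()].
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `seg_fit` with elements `model`, `curves` (tibble), `best`
#'   (epoch, val_loss, parameter snapshot) and `step_losses`.
#' @export
train_model <- function(model, data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "echoseg_model"), inherits(config, "train_config"))
  if (is.null(data$train) || dim(data$train$x)[1] < 1) stop("empty train split", call. = FALSE)
  if (is.null(data$val) || dim(data$val$x)[1] < 1) stop("empty val split", call. = FALSE)
  params <- collect_params(model)
  opt <- new_optimizer(config$optimizer, params, config$learning_rate)
  zero_grads(params)
  curves <- vector("list", config$epochs)
  step_losses <- numeric(0)
  best <- list(epoch = NA_integer_, val_loss = Inf, params = NULL, bn = NULL)
  since_best <- 0L
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ep_losses <- c()
    ep_acc <- c()
    for (ix in make_batches(dim(data$train$x)[1], config$batch_size,
                            shuffle_seed = config$seed, epoch = epoch)) {
      step <- step + 1L
      xb <- data$train$x[ix, , , , drop = FALSE]
      yb <- data$train$y[ix, , , , drop = FALSE]
      tape <- ag_tape()
      p <- fwd_model(model, tape, xb, training = TRUE)
      loss <- ag_dice_loss(tape, p, yb)
      if (!is.finite(loss$value)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", step ", step, call. = FALSE)
      }
      ag_backward(tape, loss)
      optimizer_step(opt)
      ep_losses <- c(ep_losses, loss$value)
      ep_acc <- c(ep_acc, pixel_accuracy(p$value, yb, config$threshold))
      step_losses <- c(step_losses, loss$value)
    }
    vp <- predict_batched(model, data$val$x, config$batch_size)
    val_loss <- dice_loss(vp, data$val$y)
    val_acc <- pixel_accuracy(vp, data$val$y, config$threshold)
    curves[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(ep_losses), val_loss = val_loss,
      train_accuracy = mean(ep_acc), val_accuracy = val_acc
    )
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f", epoch,
                      mean(ep_losses), val_loss))
    }
    if (val_loss < best$val_loss) {
      best <- list(epoch = epoch, val_loss = val_loss,
                   params = snapshot_params(model), bn = snapshot_bn_stats(model))
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (!is.null(config$early_stop_patience) &&
          since_best >= config$early_stop_patience) break
    }
  }
  structure(
    list(model = model, curves = dplyr::bind_rows(curves), best = best,
         step_losses = step_losses, config = config),
    class = "seg_fit"
  )
}

#' Restore the best-validation parameters into the fitted model
#'
#' @param fit A `seg_fit`.
#' @return The fit, with its model rewound to the best checkpoint.
#' @export
restore_best <- function(fit) {
  stopifnot(inherits(fit, "seg_fit"))
  restore_params(fit$model, fit$best$params)
  restore_bn_stats(fit$model, fit$best$bn)
  fit
}

#' Evaluate a model on a data split
#'
#' @param model An `echoseg_model`.
#' @param data `list(x, y)` arrays.
#' @param threshold Binarization threshold.
#' @param aggregation Passed to [evaluate_masks()].
#' @param batch_size Forward batch size.
#' @return A `metric_report`.
#' @export
evaluate_model <- function(model, data, threshold = 0.5,
                           aggregation = "per_image_mean", batch_size = 16L) {
  pred <- predict_batched(model, data$x, batch_size)
  evaluate_masks(pred, data$y, threshold, aggregation)
}

#' Build and train in one seeded call
#'
#' Seeds the RNG, builds the model (weight initialization consumes the seeded
#' stream) and trains it, so two calls with identical configs produce
#' identical fits.
#'
#' @param data As in [train_model()].
#' @param model_config A [model_config()].
#' @param config A [train_config()]; its `seed` also seeds initialization.
#' @param verbose Passed on.
#' @return A `seg_fit`.
#' @export
fit_segmentation <- function(data, model_config = model_config(),
                             config = train_config(), verbose = FALSE) {
  model <- withr::with_seed(config$seed, build_model(model_config))
  train_model(model, data, config, verbose)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architectural config, parameter values and
#' batch-norm running statistics; loading rebuilds the model and restores
#' them. A YAML copy of the config is written alongside.
#'
#' @param model An `echoseg_model`.
#' @param path Checkpoint file (`.rds`).
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "echoseg_model"))
  saveRDS(list(config = unclass(model$config), params = snapshot_params(model),
               bn = snapshot_bn_stats(model)), path)
  yaml::write_yaml(unclass(model$config), paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  ck <- readRDS(path)
  model <- build_model(do.call(model_config, ck$config))
  restore_params(model, ck$params)
  restore_bn_stats(model, ck$bn)
  model
}

#' @export
print.seg_fit <- function(x, ...) {
  cat("<seg_fit>", nrow(x$curves), "epochs;",
      "best val loss", format(x$best$val_loss, digits = 4),
      "at epoch", x$best$epoch, "\n")
  invisible(x)
}

#' Per-epoch training curves
#'
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`, `train_accuracy`,
#'   `val_accuracy`.
#' @export
tidy.seg_fit <- function(x, ...) x$curves

#' One-row training summary
#'
#' @param x A `seg_fit`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch/validation loss, final training
#'   loss and the parameter count.
#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$curves),
    best_epoch = x$best$epoch,
    best_val_loss = x$best$val_loss,
    final_train_loss = x$curves$train_loss[nrow(x$curves)],
    parameters = count_parameters(x$model)
  )
}

#' Training-curve plot
#'
#' @param object A `seg_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and pixel-accuracy curves over epochs.
#' @export
autoplot.seg_fit <- function(object, ...) {
  cv <- tidy.seg_fit(object)
  long <- tidyr::pivot_longer(cv, -"epoch", names_to = "series", values_to = "value")
  long$metric <- ifelse(grepl("loss", long$series), "loss", "pixel accuracy")
  long$phase <- ifelse(grepl("train", long$series), "train", "validation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phantom montage plot
#'
#' @param sample One sample (`list(image, mask, id)`).
#' @param ... Unused.
#' @return A ggplot showing the image with the lesion mask outline.
#' @export
plot_phantom <- function(sample, ...) {
  img <- if (dim(sample$image)[1] == 1L) sample$image[1, , ] else
    0.299 * sample$image[1, , ] + 0.587 * sample$image[2, , ] + 0.114 * sample$image[3, , ]
  d <- dim(img)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$value <- as.vector(t(img))[(df$col - 1) * d[1] + df$row]
  df$mask <- as.vector(sample$mask)[(df$col - 1) * d[1] + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sample$id, x = NULL, y = NULL, fill = "echo") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
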