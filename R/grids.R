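# Experiment grids: the ablation over module combinations, the dilation-rate
# sweep, skip-path selection and optimizer selection. Each grid enumerates
# exactly its study's configurations, trains each at the configured scale and
# returns one row of the five metrics per configuration.

#' Enumerate the configurations of an experiment grid
#'
#' @param grid One of `"modules"` (5 block combinations: baseline, each block
#'   alone, all three), `"dilation"` (the 21 strictly increasing triples
#'   `(1, d2, d3)` with `2 <= d2 < d3 <= 8`), `"skip_path"` (dual,
#'   encoder-only, decoder-only) or `"optimizer"` (adam, adagrad, adamax,
#'   rmsprop, sgd).
#' @return A tibble with a `label` column and the varied fields.
#' @export
grid_configurations <- function(grid = c("modules", "dilation", "skip_path", "optimizer")) {
  grid <- match.arg(grid)
  switch(grid,
    modules = tibble::tibble(
      label = c("baseline", "multi_receptive", "dual_scale", "skip_se", "all"),
      use_mrf = c(FALSE, TRUE, FALSE, FALSE, TRUE),
      use_dual_scale = c(FALSE, FALSE, TRUE, FALSE, TRUE),
      use_skip_se = c(FALSE, FALSE, FALSE, TRUE, TRUE)
    ),
    dilation = {
      dd <- expand.grid(d2 = 2:8, d3 = 2:8)
      dd <- dd[dd$d2 < dd$d3, ]
      dd <- dd[order(dd$d2, dd$d3), ]
      tibble::tibble(
        label = sprintf("(1, %d, %d)", dd$d2, dd$d3),
        d1 = 1L, d2 = as.integer(dd$d2), d3 = as.integer(dd$d3)
      )
    },
    skip_path = tibble::tibble(
      label = c("dual", "input1_only", "input2_only"),
      skip_path_mode = c("dual", "input1_only", "input2_only")
    ),
    optimizer = tibble::tibble(
      label = c("adam", "adagrad", "adamax", "rmsprop", "sgd"),
      optimizer = c("adam", "adagrad", "adamax", "rmsprop", "sgd")
    )
  )
}

#' Run an experiment grid
#'
#' Trains one model per grid configuration on `data` and evaluates it on
#' `data$test` (falling back to `data$val`), reporting the five metrics in
#' the conventional column order (Dice, Mcc, Jaccard, Accuracy, Recall).
#' Intended for reduced desk-scale runs; pass a full-size `model_config` and
#' `train_config` for full-scale experiments.
#'
#' @param data Named list of `train`, `val` and optionally `test` arrays.
#' @param grid Grid name, see [grid_configurations()].
#' @param base_model A [model_config()] used as the template.
#' @param base_train A [train_config()] used as the template.
#' @param verbose Print a line per configuration.
#' @return A tibble: `label`, `dice`, `mcc`, `jaccard`, `accuracy`, `recall`,
#'   `parameters`, `best_val_loss`.
#' @export
run_ablation_grid <- function(data, grid = c("modules", "dilation", "skip_path", "optimizer"),
                              base_model = model_config(), base_train = train_config(),
                              verbose = FALSE) {
  grid <- match.arg(grid)
  confs <- grid_configurations(grid)
  eval_data <- data$test %||% data$val
  rows <- vector("list", nrow(confs))
  for (i in seq_len(nrow(confs))) {
    row <- confs[i, ]
    mc <- base_model
    tc <- base_train
    if (grid == "modules") {
      mc$use_mrf <- row$use_mrf
      mc$use_dual_scale <- row$use_dual_scale
      mc$use_skip_se <- row$use_skip_se
    } else if (grid == "dilation") {
      mc$use_mrf <- TRUE
      mc$dilations <- c(row$d1, row$d2, row$d3)
    } else if (grid == "skip_path") {
      mc$use_skip_se <- TRUE
      mc$skip_path_mode <- row$skip_path_mode
    } else {
      tc$optimizer <- row$optimizer
    }
    if (verbose) message("grid ", grid, ": ", row$label)
    fit <- fit_segmentation(data, mc, tc)
    fit <- restore_best(fit)
    rep <- evaluate_model(fit$model, eval_data, threshold = tc$threshold)
    agg <- glance.metric_report(rep)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(label = row$label),
      agg[c("dice", "mcc", "jaccard", "accuracy", "recall")],
      tibble::tibble(parameters = count_parameters(fit$model),
                     best_val_loss = fit$best$val_loss)
    )
  }
  dplyr::bind_rows(rows)
}
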