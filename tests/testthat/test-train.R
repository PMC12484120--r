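# Training loop: seeded determinism, optimizer coverage, checkpointing,
# curve logging and the experiment-grid contracts, all at desk scale.

test_that("train config pins the reference defaults and validates", {
  tc <- train_config()
  expect_equal(tc$optimizer, "adam")
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$epochs, 200L)
  expect_equal(tc$batch_size, 16L)
  expect_null(tc$early_stop_patience)
  expect_error(train_config(optimizer = "lbfgs"))
  expect_error(train_config(learning_rate = 0))
})

test_that("identical seeds give identical loss sequences", {
  data <- tiny_data(n = 6, size = 16, seed = 4)
  tc <- train_config(epochs = 5, seed = 11)
  f1 <- fit_segmentation(data, tiny_model_config(), tc)
  f2 <- fit_segmentation(data, tiny_model_config(), tc)
  expect_identical(f1$step_losses[1:5], f2$step_losses[1:5])
  f3 <- fit_segmentation(data, tiny_model_config(), train_config(epochs = 5, seed = 12))
  expect_false(identical(f1$step_losses[1:5], f3$step_losses[1:5]))
})

test_that("every optimizer takes finite steps on the tiny problem", {
  data <- tiny_data(n = 4, size = 16, seed = 5)
  for (opt in c("adam", "adagrad", "adamax", "rmsprop", "sgd")) {
    fit <- fit_segmentation(data, tiny_model_config(),
                            train_config(optimizer = opt, epochs = 2, seed = 1))
    expect_true(all(is.finite(fit$step_losses)))
    expect_equal(nrow(fit$curves), 2)
  }
})

test_that("curves log one row per epoch and track both phases", {
  data <- tiny_data(n = 6, size = 16, seed = 6)
  fit <- fit_segmentation(data, tiny_model_config(), train_config(epochs = 4, seed = 2))
  cv <- tidy(fit)
  expect_equal(nrow(cv), 4)
  expect_named(cv, c("epoch", "train_loss", "val_loss", "train_accuracy",
                     "val_accuracy"))
  expect_true(all(is.finite(as.matrix(cv))))
  g <- glance(fit)
  expect_equal(g$epochs, 4)
  expect_true(g$best_epoch %in% 1:4)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("checkpoint reload reproduces the recorded best validation loss", {
  data <- tiny_data(n = 6, size = 16, seed = 7)
  fit <- fit_segmentation(data, tiny_model_config(), train_config(epochs = 3, seed = 3))
  fit <- restore_best(fit)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, ck)
  expect_true(file.exists(sub("\\.rds$", ".yaml", ck)))
  model2 <- load_checkpoint(ck)
  p2 <- echoseg:::predict_batched(model2, data$val$x)
  expect_lte(abs(dice_loss(p2, data$val$y) - fit$best$val_loss), 1e-6)
  expect_identical(predict(fit$model, data$val$x), p2)
})

test_that("early stopping halts after the configured patience", {
  data <- tiny_data(n = 6, size = 16, seed = 8)
  fit <- fit_segmentation(data, tiny_model_config(),
                          train_config(epochs = 30, seed = 4,
                                       early_stop_patience = 2))
  expect_lt(nrow(fit$curves), 30)
})

test_that("grids enumerate exactly the study configurations", {
  expect_equal(nrow(grid_configurations("modules")), 5)
  expect_equal(nrow(grid_configurations("dilation")), 21)
  expect_equal(nrow(grid_configurations("skip_path")), 3)
  expect_equal(nrow(grid_configurations("optimizer")), 5)
  expect_error(grid_configurations("tables"))
  # module rows: baseline, one per block, all three
  mods <- grid_configurations("modules")
  expect_equal(rowSums(mods[, c("use_mrf", "use_dual_scale", "use_skip_se")]),
               c(0, 1, 1, 1, 3))
})

test_that("a grid runs end to end and reports the five metrics per row", {
  data <- tiny_data(n = 8, size = 16, seed = 9)
  res <- run_ablation_grid(data, "skip_path", tiny_model_config(),
                           train_config(epochs = 2, seed = 1))
  expect_equal(nrow(res), 3)
  expect_named(res, c("label", "dice", "mcc", "jaccard", "accuracy", "recall",
                      "parameters", "best_val_loss"))
  expect_true(all(is.finite(res$dice)))
})

test_that("stubbed perfect and empty predictors hit the metric extremes", {
  data <- tiny_data(n = 4, size = 16, seed = 10)
  y <- data$val$y
  perfect <- evaluate_masks(y, y)
  g <- glance(perfect)
  expect_equal(unlist(g[c("dice", "jaccard", "accuracy", "recall")]),
               c(dice = 1, jaccard = 1, accuracy = 1, recall = 1))
  empty <- glance(evaluate_masks(array(1e-6, dim(y)), y))
  expect_equal(empty$recall, 0)
})
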