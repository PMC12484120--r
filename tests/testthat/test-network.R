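# Network assembly: configuration validation, forward contracts, exact
# parameter counting and module-ordering of parameter budgets.

test_that("model config validates its fields", {
  expect_error(model_config(in_channels = 2), "1 or 3")
  expect_error(model_config(stage_widths = c(8, 8, 16, 32)), "strictly increasing")
  expect_error(model_config(dilations = c(3, 1, 5)), "strictly increasing")
  expect_error(model_config(spatial_kernel = 4), "odd")
  cfg <- model_config()
  expect_equal(cfg$stage_widths, c(32L, 64L, 128L, 256L))
  expect_equal(cfg$dilations, c(1L, 3L, 5L))
})

test_that("baseline forward maps (1, 1, 256, 256) into sigmoid range", {
  cfg <- tiny_model_config(use_mrf = FALSE, use_dual_scale = FALSE,
                           use_skip_se = FALSE)
  model <- withr::with_seed(1, build_model(cfg))
  x <- rand_fmap(1, 1, 256, 256, seed = 2)
  p <- predict(model, x)
  expect_equal(dim(p), c(1, 1, 256, 256))
  expect_true(all(p > 0 & p < 1))
})

test_that("RGB input and batch axes follow the shape contract", {
  model <- withr::with_seed(3, build_model(tiny_model_config(in_channels = 3)))
  p <- predict(model, rand_fmap(1, 3, 64, 64, seed = 4))
  expect_equal(dim(p), c(1, 1, 64, 64))
  m2 <- withr::with_seed(5, build_model(tiny_model_config()))
  p2 <- predict(m2, rand_fmap(2, 1, 64, 64, seed = 6))
  expect_equal(dim(p2), c(2, 1, 64, 64))
  expect_error(predict(m2, rand_fmap(1, 1, 60, 60, seed = 7)), "divisible by 8")
})

test_that("forward is deterministic in evaluation mode", {
  model <- withr::with_seed(8, build_model(tiny_model_config()))
  x <- rand_fmap(1, 1, 32, 32, seed = 9)
  expect_identical(predict(model, x), predict(model, x))
})

test_that("parameter counting is exact for single layers", {
  conv1 <- withr::with_seed(1, echoseg:::new_conv2d(1, 1, 1))
  expect_equal(echoseg:::n_params(conv1), 2) # 1 weight + 1 bias
  conv2 <- withr::with_seed(1, echoseg:::new_conv2d(2, 4, 3))
  expect_equal(echoseg:::n_params(conv2), 3 * 3 * 2 * 4 + 4)
})

test_that("each enabled block adds parameters and the full model has most", {
  counts <- vapply(
    list(
      model_config(use_mrf = FALSE, use_dual_scale = FALSE, use_skip_se = FALSE),
      model_config(use_mrf = TRUE, use_dual_scale = FALSE, use_skip_se = FALSE),
      model_config(use_mrf = FALSE, use_dual_scale = TRUE, use_skip_se = FALSE),
      model_config(use_mrf = FALSE, use_dual_scale = FALSE, use_skip_se = TRUE),
      model_config()
    ),
    function(cfg) count_parameters(withr::with_seed(1, build_model(cfg))),
    numeric(1)
  )
  expect_true(all(counts[2:4] > counts[1]))
  expect_true(all(counts[5] > counts[1:4]))
  # the default width schedule lands in the low-millions regime
  expect_gt(counts[1], 1e6)
  expect_lt(counts[5], 1e7)
})
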