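# Phantom generator: seeded determinism, geometry and intensity properties,
# and the split contract.

test_that("generation is a pure function of the config", {
  cfg <- phantom_config(n_images = 4, size = 64, seed = 7)
  a <- generate_phantoms(cfg)
  b <- generate_phantoms(cfg)
  expect_identical(a[[1]]$image, b[[1]]$image)
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
  expect_equal(length(a), 4)
})

test_that("config validation rejects impossible geometry and ranges", {
  expect_error(phantom_config(lesion_axis_fraction = c(0.1, 0.6)), "below 0.5")
  expect_error(phantom_config(contrast_drop = 1.2), "contrast_drop")
  expect_error(phantom_config(speckle_shape = 0), "positive")
  expect_error(phantom_config(blur_sigma = -1), "nonnegative")
})

test_that("images are in [0, 1] with binary nonempty masks", {
  ph <- generate_phantoms(phantom_config(n_images = 3, size = 48, seed = 2))
  for (s in ph) {
    expect_true(all(s$image >= 0 & s$image <= 1))
    expect_true(all(s$mask %in% c(0L, 1L)))
    expect_gt(sum(s$mask), 0)
    expect_equal(dim(s$image), c(1, 48, 48))
  }
  rgb <- generate_phantoms(phantom_config(n_images = 1, size = 32, seed = 3,
                                          rgb = TRUE))
  expect_equal(dim(rgb[[1]]$image), c(3, 32, 32))
})

test_that("single fixed-axis lesions rasterize close to the analytic area", {
  target <- pi * (0.1 * 64)^2
  areas <- vapply(1:50, function(s) {
    ph <- generate_phantoms(phantom_config(
      n_images = 1, size = 64, seed = s, lesions_per_image = c(1, 1),
      lesion_axis_fraction = c(0.1, 0.1)
    ))
    sum(ph[[1]]$mask)
  }, numeric(1))
  expect_true(all(areas >= 0.7 * target & areas <= 1.3 * target))
})

test_that("lesion contrast falls monotonically with contrast_drop", {
  ratio <- function(drop) {
    mean(vapply(1:20, function(s) {
      ph <- generate_phantoms(phantom_config(
        n_images = 1, size = 48, seed = 500 + s, contrast_drop = drop,
        speckle_shape = Inf, blur_sigma = 0
      ))[[1]]
      mean(ph$image[1, , ][ph$mask == 1]) / mean(ph$image[1, , ][ph$mask == 0])
    }, numeric(1)))
  }
  r <- c(ratio(0.15), ratio(0.45), ratio(0.75))
  expect_true(all(diff(r) < 0))
  # contrast_drop = 0: lesion indistinguishable from background in expectation
  expect_lt(abs(ratio(0) - 1), 0.05)
})

test_that("speckle variance grows as the gamma shape shrinks", {
  specvar <- function(shape) {
    mean(vapply(1:10, function(s) {
      ph <- generate_phantoms(phantom_config(
        n_images = 1, size = 48, seed = 700 + s, speckle_shape = shape,
        blur_sigma = 0, contrast_drop = 0, lesions_per_image = c(1, 1)
      ))[[1]]
      stats::var(as.vector(ph$image))
    }, numeric(1)))
  }
  v <- c(specvar(16), specvar(4), specvar(1))
  expect_true(all(diff(v) > 0))
})

test_that("split is a seeded, disjoint, exhaustive partition", {
  ph <- generate_phantoms(phantom_config(n_images = 10, size = 16, seed = 1))
  sp <- split_samples(ph, c(0.6, 0.2, 0.2), seed = 5)
  expect_equal(lengths(sp), c(train = 6L, val = 2L, test = 2L))
  sp2 <- split_samples(ph, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(lapply(sp$train, `[[`, "id"), lapply(sp2$train, `[[`, "id"))
  ids <- unlist(lapply(unlist(sp, recursive = FALSE), `[[`, "id"))
  expect_setequal(ids, vapply(ph, `[[`, "", "id"))
  expect_equal(anyDuplicated(ids), 0)
  expect_error(split_samples(ph, c(0.5, 0.2, 0.2)), "summing to 1")
})
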