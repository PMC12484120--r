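# Dual-scale attention block: extent preservation (including odd sizes),
# constant-field round trips, closed-form cascade with neutral parameters,
# and finiteness over random configurations.

test_that("output extents equal input extents for both upsample modes", {
  for (mode in c("bilinear", "nearest")) {
    blk <- withr::with_seed(1, echoseg:::new_dual_scale_block(
      3, 5, reduction = 2, spatial_kernel = 3, upsample_mode = mode))
    y <- echoseg:::fwd_dual_scale_block(blk, NULL, rand_fmap(1, 3, 16, 16, seed = 2), FALSE)
    expect_equal(dim(y), c(1, 5, 16, 16))
    # odd extents: the 2x branch resizes back to the exact native shape
    y15 <- echoseg:::fwd_dual_scale_block(blk, NULL, rand_fmap(1, 3, 15, 15, seed = 3), FALSE)
    expect_equal(dim(y15), c(1, 5, 15, 15))
  }
  blk <- withr::with_seed(1, echoseg:::new_dual_scale_block(3, 5))
  expect_error(echoseg:::fwd_dual_scale_block(blk, NULL, rand_fmap(1, 3, 1, 1), FALSE),
               ">= 2")
})

test_that("nearest upsample then box-average downsample is exact on any field", {
  x <- rand_fmap(2, 3, 4, 4, seed = 4)
  up <- echoseg:::ag_resize(NULL, x, 8, 8, "nearest")
  dn <- echoseg:::ag_resize(NULL, up, 4, 4, "area")
  expect_equal(dn, x, tolerance = 1e-14)
  # constant field: bilinear round trip is also exact
  xc <- array(0.7, c(1, 2, 6, 6))
  upc <- echoseg:::ag_resize(NULL, xc, 12, 12, "bilinear")
  expect_true(all(abs(upc - 0.7) < 1e-12))
})

test_that("neutralised block computes the closed-form 0.75x cascade", {
  # identity convolutions, zeroed attention (gates 0.5), nearest 2x branch:
  # scale A -> 1.5x, scale B folds back to 1.5x, fusion 3x, then the two
  # attention stages scale by 0.5 each: output 0.75x on nonnegative input.
  blk <- withr::with_seed(5, echoseg:::new_dual_scale_block(
    1, 1, reduction = 1, spatial_kernel = 3, upsample_mode = "nearest"))
  idk <- array(0, c(3, 3, 1, 1)); idk[2, 2, 1, 1] <- 1
  for (cv in list(blk$conv_a, blk$conv_b, blk$conv1, blk$conv2)) {
    cv$conv$W$value <- idk
    cv$conv$b$value[] <- 0
  }
  for (a in list(blk$ca_a, blk$ca_b, blk$ca1, blk$sa2)) echoseg:::zero_params(a)
  for (l in echoseg:::collect_bn_layers(blk)) l$eps <- 0 # exact identity in eval mode
  x <- abs(rand_fmap(1, 1, 4, 4, seed = 6))
  got <- echoseg:::fwd_dual_scale_block(blk, NULL, x, training = FALSE)
  expect_equal(got, 0.75 * x, tolerance = 1e-12)
})

test_that("random configurations stay finite", {
  for (i in 1:100) {
    cfg <- withr::with_seed(1000 + i, list(
      cin = sample(1:6, 1), cout = sample(1:6, 1),
      red = sample(1:4, 1), h = sample(4:11, 1), w = sample(4:11, 1),
      mode = sample(c("bilinear", "nearest"), 1)
    ))
    blk <- withr::with_seed(2000 + i, echoseg:::new_dual_scale_block(
      cfg$cin, cfg$cout, cfg$red, 3, cfg$mode))
    x <- rand_fmap(1, cfg$cin, cfg$h, cfg$w, seed = 3000 + i)
    y <- echoseg:::fwd_dual_scale_block(blk, NULL, x, training = FALSE)
    expect_true(all(is.finite(y)))
    expect_equal(dim(y), c(1, cfg$cout, cfg$h, cfg$w))
  }
})
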