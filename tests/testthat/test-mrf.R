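# Multi-receptive fusion block: dilated-convolution correctness against a
# loop oracle, closed-form impulse response with neutralised parameters,
# dilation-sweep robustness and gradient flow to all branches.

test_that("compiled dilated convolution matches the naive loop oracle", {
  for (dil in c(1, 3, 5)) {
    x <- rand_fmap(2, 3, 9, 9, seed = dil)
    W <- withr::with_seed(10 + dil, array(stats::rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)))
    b <- withr::with_seed(20 + dil, stats::rnorm(4))
    got <- echoseg:::.conv2d_fw(x, W, b, dil)
    want <- naive_conv(x, W, b, dil)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})

test_that("dilated impulse response has the expected tap offsets", {
  # a 3x3 kernel at dilation d reads taps at offsets {-d, 0, d}: the
  # effective receptive side is 3 + 2(d - 1)
  for (dil in c(2, 4)) {
    x <- array(0, c(1, 1, 13, 13))
    x[1, 1, 7, 7] <- 1
    W <- array(1, c(3, 3, 1, 1))
    y <- echoseg:::.conv2d_fw(x, W, 0, dil)
    nz <- which(y[1, 1, , ] != 0, arr.ind = TRUE)
    expect_setequal(unique(nz[, 1]), 7 + c(-dil, 0, dil))
    expect_setequal(unique(nz[, 2]), 7 + c(-dil, 0, dil))
  }
})

test_that("neutralised block reduces to a closed-form impulse multiple", {
  # identity-passing convolutions + zeroed attention (every gate = 0.5) in
  # evaluation mode: branch outputs are 0.5x, 0.75x, 1.125x, the sum-fused
  # map is 3.375x and the final gate leaves 1.6875x.
  blk <- withr::with_seed(1, echoseg:::new_mrf_block(1, 1, c(1, 3, 5)))
  idk <- array(0, c(3, 3, 1, 1)); idk[2, 2, 1, 1] <- 1
  blk$entry$conv$W$value <- array(1, c(1, 1, 1, 1))
  blk$b1$conv$W$value <- idk
  blk$b2$conv$W$value <- idk
  blk$b3$conv$W$value <- idk
  blk$fuse$conv$W$value <- array(1, c(1, 1, 4, 1))
  for (l in list(blk$entry, blk$b1, blk$b2, blk$b3, blk$fuse)) l$conv$b$value[] <- 0
  for (a in list(blk$sa1, blk$ca2, blk$sa3, blk$sa_out)) echoseg:::zero_params(a)
  for (l in echoseg:::collect_bn_layers(blk)) l$eps <- 0 # exact identity in eval mode

  x <- array(0, c(1, 1, 13, 13))
  x[1, 1, 7, 7] <- 1
  got <- echoseg:::fwd_mrf_block(blk, NULL, x, training = FALSE)
  expect_equal(got, 1.6875 * x, tolerance = 1e-12)

  # independent oracle: the same pipeline evaluated with the loop-based
  # dilated convolution
  oc <- function(z, d) naive_conv(z, idk, 0, d)
  main <- x
  y1 <- 0.5 * oc(main, 1)
  y2 <- 0.5 * oc(main + y1, 3)
  y3 <- 0.5 * oc(main + y1 + y2, 5)
  want <- 0.5 * (y1 + y2 + y3 + main)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("all 21 dilation triples of the sweep run and preserve extents", {
  confs <- grid_configurations("dilation")
  expect_equal(nrow(confs), 21L)
  expect_equal(confs$label[1], "(1, 2, 3)")
  expect_equal(confs$label[21], "(1, 7, 8)")
  x <- rand_fmap(1, 4, 32, 32, seed = 9)
  for (i in seq_len(nrow(confs))) {
    blk <- withr::with_seed(i, echoseg:::new_mrf_block(
      4, 8, c(confs$d1[i], confs$d2[i], confs$d3[i]), reduction = 4,
      spatial_kernel = 3))
    y <- echoseg:::fwd_mrf_block(blk, NULL, x, training = FALSE)
    expect_equal(dim(y), c(1, 8, 32, 32))
    expect_true(all(is.finite(y)))
  }
})

test_that("gradients flow to every branch after one optimisation step", {
  # reduction 1 keeps the attention bottleneck wide enough that the rectifier
  # cannot silence the whole hidden layer on a tiny example
  blk <- withr::with_seed(2, echoseg:::new_mrf_block(3, 6, reduction = 1,
                                                     spatial_kernel = 3))
  x <- rand_fmap(2, 3, 12, 12, seed = 3)
  tape <- echoseg:::ag_tape()
  y <- echoseg:::fwd_mrf_block(blk, tape, echoseg:::ag_const(tape, x), training = TRUE)
  loss <- echoseg:::ag_dice_loss(tape, echoseg:::ag_sigmoid(tape, y),
                                 array(1, c(2, 6, 12, 12)))
  echoseg:::ag_backward(tape, loss)
  for (part in c("entry", "b1", "b2", "b3", "fuse")) {
    expect_gt(sqrt(sum(blk[[part]]$conv$W$grad^2)), 0)
  }
  for (part in c("sa1", "sa3", "sa_out")) {
    expect_gt(sqrt(sum(blk[[part]]$conv$W$grad^2)), 0)
  }
  expect_gt(sqrt(sum(blk$ca2$fc1$W$grad^2)), 0)
})

test_that("block validates channel and dilation configuration", {
  expect_error(echoseg:::new_mrf_block(4, 8, c(1, 1, 5)), "strictly increasing")
  blk <- withr::with_seed(1, echoseg:::new_mrf_block(4, 8, spatial_kernel = 3))
  expect_error(echoseg:::fwd_mrf_block(blk, NULL, rand_fmap(1, 3, 8, 8), FALSE),
               "expected 4 channels")
  r <- multi_receptive_fusion(rand_fmap(1, 64, 16, 16, seed = 1), out_channels = 64)
  expect_equal(dim(r$output), c(1, 64, 16, 16))
})
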