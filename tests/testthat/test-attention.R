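# Attention primitives: shape contracts, sigmoid-gate identities, and
# equivalence with direct evaluation of the pooled-descriptor bottleneck.

test_that("spatial attention obeys the shape contract and gate identities", {
  x <- rand_fmap(2, 8, 4, 4, seed = 1)
  sa <- spatial_attention(x)
  expect_equal(dim(sa$weights), c(2, 1, 4, 4))
  expect_equal(dim(sa$output), dim(x))
  expect_true(all(sa$weights > 0 & sa$weights < 1))

  # zeroed filter parameters: sigmoid(0) = 0.5 everywhere, y = x/2
  echoseg:::zero_params(sa$module)
  sa0 <- spatial_attention(x, module = sa$module)
  expect_equal(as.vector(sa0$weights), rep(0.5, 2 * 16))
  expect_equal(sa0$output, 0.5 * x)

  # spatially constant input -> constant weights away from padding
  xc <- array(rep(withr::with_seed(3, stats::rnorm(16)), times = 25), c(2, 8, 5, 5))
  m <- withr::with_seed(3, echoseg:::new_spatial_attention(3L))
  wc <- spatial_attention(xc, module = m)$weights
  interior <- wc[, , 2:4, 2:4, drop = FALSE]
  expect_lt(max(abs(interior - as.vector(interior[, 1, 1, 1]))), 1e-12)

  expect_error(spatial_attention(x, kernel = 4), "odd")
})

test_that("channel attention matches direct evaluation of the shared bottleneck", {
  x <- rand_fmap(1, 16, 8, 8, seed = 2)
  ca <- channel_attention(x, reduction = 8)
  expect_equal(dim(ca$weights), c(1, 16, 1, 1))
  expect_true(all(ca$weights > 0 & ca$weights < 1))

  echoseg:::zero_params(ca$module)
  ca0 <- channel_attention(x, module = ca$module)
  expect_equal(as.vector(ca0$weights), rep(0.5, 16))
  expect_equal(ca0$output, 0.5 * x)
  expect_error(channel_attention(x, reduction = 0), "positive")

  # identity bottleneck (hid = C, identity weights): the gate must equal
  # sigmoid(relu(avg) + relu(max)) computed directly from pooled descriptors,
  # and permuting channels must permute the gate identically.
  x <- rand_fmap(2, 6, 5, 5, seed = 4)
  m <- echoseg:::new_channel_attention(6, reduction = 1)
  m$fc1$W$value <- diag(6)
  m$fc2$W$value <- diag(6)
  m$fc1$b$value[] <- 0
  m$fc2$b$value[] <- 0
  got <- channel_attention(x, module = m)$weights
  avg <- apply(x, c(1, 2), mean)
  mx <- apply(x, c(1, 2), max)
  want <- 1 / (1 + exp(-(pmax(avg, 0) + pmax(mx, 0))))
  expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)

  perm <- c(3, 1, 6, 2, 5, 4)
  got_p <- channel_attention(x[, perm, , , drop = FALSE], module = m)$weights
  expect_equal(as.vector(got_p), as.vector(got[, perm, , , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("SE block is channel attention without the max-pool path", {
  x <- rand_fmap(1, 32, 4, 4, seed = 5)
  se <- se_block(x, reduction = 8)
  expect_equal(dim(se$weights), c(1, 32, 1, 1))
  expect_equal(dim(se$output), dim(x))

  echoseg:::zero_params(se$module)
  expect_equal(se_block(x, module = se$module)$output, 0.5 * x)

  # zero input with zero biases: squeeze descriptor 0, gate 0.5, output 0
  z <- array(0, c(1, 8, 4, 4))
  sez <- withr::with_seed(6, se_block(z, reduction = 4))
  expect_equal(as.vector(sez$weights), rep(0.5, 8))
  expect_true(all(sez$output == 0))

  # with the max-pool contribution forced to zero (x <= 0 with per-channel
  # max exactly 0) and matched bottlenecks, SE and channel attention agree
  x2 <- -abs(rand_fmap(2, 8, 4, 4, seed = 7))
  x2[, , 1, 1] <- 0
  ca <- withr::with_seed(8, echoseg:::new_channel_attention(8, 4))
  se2 <- echoseg:::new_se_block(8, 4)
  se2$fc1 <- ca$fc1
  se2$fc2 <- ca$fc2
  wca <- channel_attention(x2, module = ca)$weights
  wse <- se_block(x2, module = se2)$weights
  expect_equal(wca, wse, tolerance = 1e-12)
})

test_that("attention gates stay in (0, 1) and preserve extents over random cases", {
  for (i in 1:10) {
    d <- withr::with_seed(100 + i, c(sample(1:3, 1), sample(2:12, 1),
                                     sample(3:9, 1), sample(3:9, 1)))
    x <- rand_fmap(d[1], d[2], d[3], d[4], seed = 200 + i)
    withr::with_seed(300 + i, {
      for (r in list(spatial_attention(x, kernel = 3),
                     channel_attention(x, reduction = 4),
                     se_block(x, reduction = 4))) {
        expect_equal(dim(r$output), d)
        expect_true(all(r$weights > 0 & r$weights < 1))
        expect_true(all(is.finite(r$output)))
      }
    })
  }
})
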