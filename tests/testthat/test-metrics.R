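# Dice loss identities, confusion-count correctness against a pixel-loop
# oracle, the five metrics, their algebraic couplings and the aggregation
# modes.

test_that("dice loss satisfies its closed-form identities", {
  y <- rand_mask(8, 8, seed = 1)
  expect_lt(dice_loss(y, y), 1e-6)
  expect_gt(dice_loss(0 * y, y), 1 - 1e-6)
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 0.5, tolerance = 1e-9)
  expect_error(dice_loss(c(0.5), c(1, 0)), "extents differ")
  expect_error(dice_loss(c(1.5, 0), c(1, 0)), "lie in")
  # empty-vs-empty is a perfect match under the smoothing constant
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)
})

test_that("confusion counts equal the nested-loop tally", {
  cc <- confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 4, tn = 0, fp = 0, fn = 0))
  cc2 <- confusion_counts(matrix(1, 2, 2), matrix(0, 2, 2))
  expect_equal(cc2$fp, 4)
  expect_equal(cc2$tp + cc2$tn + cc2$fn, 0)
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")

  for (i in 1:20) {
    p <- rand_mask(16, 16, seed = 40 + i)
    y <- rand_mask(16, 16, seed = 80 + i)
    got <- confusion_counts(p, y)
    want <- naive_counts(p, y)
    expect_equal(unlist(got[c("tp", "tn", "fp", "fn")]), want)
    expect_equal(got$n, 256)
  }
})

test_that("metrics match direct substitution and conventions", {
  m <- metrics_from_counts(data.frame(tp = 3, fp = 1, fn = 1, tn = 11))
  expect_equal(m$dice, 0.75)
  expect_equal(m$jaccard, 0.6)
  expect_equal(m$recall, 0.75)
  expect_equal(m$accuracy, 0.875)

  expect_equal(metrics_from_counts(data.frame(tp = 5, tn = 5, fp = 0, fn = 0))$mcc, 1)
  expect_equal(metrics_from_counts(data.frame(tp = 2, tn = 3, fp = 1, fn = 1))$mcc,
               5 / 12, tolerance = 1e-12)

  # degenerate-denominator conventions
  empty <- metrics_from_counts(data.frame(tp = 0, tn = 9, fp = 0, fn = 0))
  expect_equal(empty$dice, 1)
  expect_equal(empty$jaccard, 1)
  expect_equal(empty$recall, 1)
  expect_equal(empty$mcc, 0)
})

test_that("jaccard-dice identity and mcc-pearson identity hold on random cases", {
  for (i in 1:50) {
    cts <- withr::with_seed(200 + i, data.frame(
      tp = sample(0:50, 1), tn = sample(1:50, 1),
      fp = sample(0:50, 1), fn = sample(1:50, 1)
    ))
    m <- metrics_from_counts(cts)
    expect_equal(m$jaccard, m$dice / (2 - m$dice), tolerance = 1e-12)
  }
  for (i in 1:20) {
    p <- rand_mask(12, 12, p = 0.5, seed = 300 + i)
    y <- rand_mask(12, 12, p = 0.5, seed = 400 + i)
    if (length(unique(as.vector(p))) < 2 || length(unique(as.vector(y))) < 2) next
    m <- metrics_from_counts(confusion_counts(p, y))
    expect_equal(m$mcc, stats::cor(as.vector(p), as.vector(y)), tolerance = 1e-10)
  }
})

test_that("evaluation binarizes, aggregates per image and pools globally", {
  pred <- array(0.9, c(1, 1, 4, 4))
  y <- array(1, c(1, 1, 4, 4))
  expect_equal(glance(evaluate_masks(pred, y))$dice, 1)

  # two images engineered to per-image dice 1.0 and 0.5
  pred2 <- array(0, c(2, 1, 2, 2))
  y2 <- array(0, c(2, 1, 2, 2))
  pred2[1, 1, , ] <- 1; y2[1, 1, , ] <- 1
  pred2[2, 1, , ] <- c(1, 1, 0, 0); y2[2, 1, , ] <- c(1, 0, 1, 0)
  rep_mean <- evaluate_masks(pred2, y2, aggregation = "per_image_mean")
  expect_equal(rep_mean$dice, c(1, 0.5))
  expect_equal(glance(rep_mean)$dice, 0.75)

  rep_pool <- evaluate_masks(pred2, y2, aggregation = "global_pool")
  pooled <- metrics_from_counts(data.frame(
    tp = sum(rep_pool$tp), tn = sum(rep_pool$tn),
    fp = sum(rep_pool$fp), fn = sum(rep_pool$fn)
  ))
  expect_equal(glance(rep_pool)$dice, pooled$dice)
  expect_false(isTRUE(all.equal(glance(rep_pool)$dice, 0.75)))

  expect_error(evaluate_masks(list(), list()), "empty batch")
  expect_error(evaluate_masks(pred, y, threshold = 1), "strictly in")
})

test_that("metric reports write CSV and JSON with an aggregate row", {
  pred <- array(stats::runif(2 * 16), c(2, 1, 4, 4))
  y <- array(rand_mask(4, 8, seed = 5), c(2, 1, 4, 4))
  rep <- evaluate_masks(pred, y)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_metric_report(rep, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$image[3], "aggregate")
  agg <- jsonlite::read_json(js)
  expect_equal(agg$dice, glance(rep)$dice, tolerance = 1e-12)
})
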