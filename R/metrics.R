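# Dice loss and the five-metric evaluation suite (Dice, Matthews correlation,
# Jaccard, accuracy, recall) computed from per-image pixel confusion counts.

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)`, the complement of
#' the soft Dice overlap between a probability map and a binary mask. The
#' smoothing constant `eps` makes the empty-vs-empty case evaluate to 0; it
#' is kept at `1e-9` so nonempty masks are perturbed by less than `1e-9`
#' while the degenerate case stays defined.
#' When `p` has a leading batch axis the loss is the mean of per-image losses.
#'
#' @param p Numeric array of predictions in `[0, 1]`.
#' @param y Binary array of the same extents.
#' @param eps Smoothing constant (default `1e-9`).
#' @param batched If `TRUE` (default for rank-4 input) the first axis indexes
#'   images and the result is the per-image mean.
#' @return A single number in `[0, 1]`.
#' @examples
#' dice_loss(c(0.5, 0.5), c(1, 0)) # 0.5
#' @export
dice_loss <- function(p, y, eps = 1e-9, batched = length(dim(p)) == 4L) {
  if (!identical(length(p), length(y))) {
    stop("prediction and mask extents differ", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]", call. = FALSE)
  if (batched) {
    N <- dim(p)[1]
    pm <- matrix(p, nrow = N)
    ym <- matrix(y, nrow = N)
    li <- 1 - (2 * rowSums(pm * ym) + eps) / (rowSums(pm) + rowSums(ym) + eps)
    mean(li)
  } else {
    1 - (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
  }
}

#' Pixel confusion counts of a binary prediction
#'
#' @param pred Binary array (values 0/1 or logical).
#' @param y Binary reference array of identical extents.
#' @return A tibble with one row: `tp`, `tn`, `fp`, `fn`, `n` (total pixels).
#' @export
confusion_counts <- function(pred, y) {
  if (!identical(length(pred), length(y))) {
    stop("prediction and mask extents differ", call. = FALSE)
  }
  pv <- as.vector(pred); yv <- as.vector(y)
  if (!all(pv %in% c(0, 1)) || !all(yv %in% c(0, 1))) {
    stop("confusion_counts() needs binary inputs", call. = FALSE)
  }
  tp <- sum(pv == 1 & yv == 1)
  tn <- sum(pv == 0 & yv == 0)
  fp <- sum(pv == 1 & yv == 0)
  fn <- sum(pv == 0 & yv == 1)
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn, n = tp + tn + fp + fn)
}

#' Segmentation metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FN+FP); Mcc = (TP*TN - FP*FN) /
#' sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)); Jaccard = TP/(TP+FN+FP);
#' Accuracy = (TP+TN)/(TP+TN+FN+FP); Recall = TP/(TP+FN).
#' Degenerate denominators follow the standard conventions: Dice, Jaccard and
#' recall are 1 when the relevant denominator is 0 (nothing to find, nothing
#' found), and Mcc is 0 when any marginal is 0.
#'
#' @param counts A data frame with columns `tp`, `tn`, `fp`, `fn` (one row per
#'   image), e.g. from [confusion_counts()].
#' @return A tibble with columns `dice`, `mcc`, `jaccard`, `accuracy`,
#'   `recall`, one row per input row.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(tp + tn + fp + fn < 1)) stop("at least one pixel required", call. = FALSE)
  safe <- function(num, den) ifelse(den == 0, 1, num / den)
  mden2 <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  tibble::tibble(
    dice = safe(2 * tp, 2 * tp + fn + fp),
    mcc = ifelse(mden2 == 0, 0, (tp * tn - fp * fn) / sqrt(mden2)),
    jaccard = safe(tp, tp + fn + fp),
    accuracy = (tp + tn) / (tp + tn + fn + fp),
    recall = safe(tp, tp + fn)
  )
}

#' Evaluate predicted probability maps against reference masks
#'
#' Binarizes predictions at `threshold`, tallies per-image confusion counts
#' and reports the five metrics per image plus an aggregate row.
#' `per_image_mean` averages per-image metrics; `global_pool` sums the counts
#' over all images first and computes the metrics once on the pooled tallies.
#'
#' @param pred `(batch, 1, H, W)` array of probabilities (or a list of 2-D
#'   maps).
#' @param y Matching binary masks.
#' @param threshold Binarization threshold in (0, 1), default 0.5.
#' @param aggregation `"per_image_mean"` (default) or `"global_pool"`.
#' @return A `metric_report`: a tibble with columns `image`, `tp`, `tn`,
#'   `fp`, `fn`, `dice`, `mcc`, `jaccard`, `accuracy`, `recall`; the aggregate
#'   is available via [glance.metric_report()].
#' @export
evaluate_masks <- function(pred, y, threshold = 0.5,
                           aggregation = c("per_image_mean", "global_pool")) {
  aggregation <- match.arg(aggregation)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.array(pred) && length(dim(pred)) == 4L) {
    n <- dim(pred)[1]
    pred <- lapply(seq_len(n), function(i) pred[i, 1, , ])
  }
  if (is.array(y) && length(dim(y)) == 4L) {
    y <- lapply(seq_len(dim(y)[1]), function(i) y[i, 1, , ])
  } else if (is.array(y) && length(dim(y)) == 3L) {
    y <- lapply(seq_len(dim(y)[1]), function(i) y[i, , ])
  }
  if (length(pred) == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(pred) == length(y))
  rows <- purrr::map2_dfr(pred, y, function(p, m) {
    confusion_counts(1 * (p > threshold), m)
  })
  per_image <- dplyr::bind_cols(
    tibble::tibble(image = seq_len(nrow(rows))), rows,
    metrics_from_counts(rows)
  )
  structure(per_image,
            class = c("metric_report", class(per_image)),
            aggregation = aggregation, threshold = threshold)
}

metric_names <- c("dice", "mcc", "jaccard", "accuracy", "recall")

#' Aggregate row of a metric report
#'
#' @param x A `metric_report` from [evaluate_masks()].
#' @param ... Unused.
#' @return One-row tibble with the five aggregated metrics, `n_images` and
#'   the aggregation mode.
#' @export
glance.metric_report <- function(x, ...) {
  agg <- attr(x, "aggregation")
  vals <- if (identical(agg, "global_pool")) {
    pooled <- dplyr::summarise(x, dplyr::across(dplyr::all_of(c("tp", "tn", "fp", "fn")), sum))
    metrics_from_counts(pooled)
  } else {
    dplyr::summarise(x, dplyr::across(dplyr::all_of(metric_names), mean))
  }
  dplyr::bind_cols(vals, tibble::tibble(n_images = nrow(x), aggregation = agg))
}

#' Per-image rows of a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The per-image tibble (one row per image).
#' @export
tidy.metric_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Write a metric report to CSV and JSON
#'
#' The CSV holds one row per image plus an `aggregate` row; the JSON mirrors
#' the aggregate.
#'
#' @param report A `metric_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  agg <- glance.metric_report(report)
  if (!is.null(csv_path)) {
    per <- tidy.metric_report(report)
    per$image <- as.character(per$image)
    aggrow <- tibble::tibble(image = "aggregate", tp = NA, tn = NA, fp = NA, fn = NA)
    aggrow <- dplyr::bind_cols(aggrow, agg[metric_names])
    utils::write.csv(dplyr::bind_rows(per, aggrow), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(agg), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
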