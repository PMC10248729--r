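# Pixel-level evaluation metrics and training losses.
#
# All functions take a prediction (probability map in [0, 1]) and a ground
# truth mask in {0, 1} of the same shape. "Hard" scores binarize the
# prediction at a threshold first; "soft" scores use the raw probabilities
# in the sums. An epsilon in numerator and denominator defines the
# empty-vs-empty case of the overlap scores as 1.

check_pair <- function(prediction, truth) {
  if (length(prediction) == 0L) stop("metrics: empty image")
  if (!all(dim(prediction) == dim(truth)) && length(prediction) != length(truth))
    stop("metrics: prediction and truth shapes differ")
  if (any(prediction < -1e-12) || any(prediction > 1 + 1e-12))
    stop("metrics: prediction values must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("metrics: truth must be binary")
  invisible(NULL)
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` over all pixels, after binarizing the
#' prediction at `threshold`.
#'
#' @param prediction Probability map in [0, 1].
#' @param truth Binary mask in \{0, 1\}.
#' @param threshold Binarization threshold.
#' @return Fraction in [0, 1].
#' @export
seg_accuracy <- function(prediction, truth, threshold = 0.5) {
  check_pair(prediction, truth)
  mean((prediction >= threshold) == (truth == 1))
}

#' Dice coefficient
#'
#' `2 * sum(p * y) / (sum(p) + sum(y))`, with smoothing `eps` so that two
#' empty masks score 1.
#'
#' @inheritParams seg_accuracy
#' @param soft Use raw probabilities (`TRUE`) or binarize first (`FALSE`).
#' @param eps Smoothing constant.
#' @return Score in [0, 1].
#' @export
dice_score <- function(prediction, truth, soft = FALSE, threshold = 0.5,
                       eps = 1e-7) {
  check_pair(prediction, truth)
  p <- if (soft) as.numeric(prediction) else as.numeric(prediction >= threshold)
  y <- as.numeric(truth)
  (2 * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

#' Jaccard index
#'
#' `sum(y * p) / (sum(y) + sum(p) - sum(y * p))` with the same smoothing
#' convention as [dice_score()]. On binary inputs `J = D / (2 - D)`.
#'
#' @inheritParams dice_score
#' @return Score in [0, 1].
#' @export
jaccard_score <- function(prediction, truth, soft = FALSE, threshold = 0.5,
                          eps = 1e-7) {
  check_pair(prediction, truth)
  p <- if (soft) as.numeric(prediction) else as.numeric(prediction >= threshold)
  y <- as.numeric(truth)
  inter <- sum(p * y)
  (inter + eps) / (sum(p) + sum(y) - inter + eps)
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood per pixel, with the prediction clipped to
#' `[clip, 1 - clip]` before the logarithms.
#'
#' @inheritParams seg_accuracy
#' @param clip Clipping constant.
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(prediction, truth, clip = 1e-7) {
  check_pair(prediction, truth)
  p <- pmin(pmax(as.numeric(prediction), clip), 1 - clip)
  y <- as.numeric(truth)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice and Jaccard losses
#'
#' `1 - soft Dice` and `1 - soft Jaccard`.
#' @inheritParams seg_accuracy
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(prediction, truth)
  1 - dice_score(prediction, truth, soft = TRUE)

#' @rdname dice_loss
#' @export
jaccard_loss <- function(prediction, truth)
  1 - jaccard_score(prediction, truth, soft = TRUE)

# Gradient of each training loss with respect to the predicted
# probabilities (same shape as the prediction); used to seed backprop.
loss_grad <- function(loss_name, p, y) {
  n <- length(p)
  switch(loss_name,
         bce = (p - y) / n,  # seeded at the logits (sigmoid folded in)
         dice = {
           sp <- sum(p) + sum(y) + 1e-7
           si <- 2 * sum(p * y) + 1e-7
           -(2 * y * sp - si) / sp^2
         },
         jaccard = {
           inter <- sum(p * y)
           un <- sum(p) + sum(y) - inter + 1e-7
           -(y * un - (inter + 1e-7) * (1 - y)) / un^2
         },
         stop("unknown loss: ", loss_name))
}

loss_value <- function(loss_name, p, y) {
  switch(loss_name,
         bce = bce_loss(p, y),
         dice = dice_loss(p, y),
         jaccard = jaccard_loss(p, y))
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the per-patch scores with replacement `n_boot` times and
#' returns the 2.5th and 97.5th percentiles of the resampled means.
#'
#' @param values Numeric vector of per-patch scores (length >= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, seed = 1L) {
  if (length(values) < 2L) stop("bootstrap_ci: need at least 2 values")
  means <- with_seed(seed, {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) mean(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Build a metric report from per-patch scores
#'
#' @param per_patch Data frame with columns `accuracy`, `dice`, `jaccard`
#'   (fractions in [0, 1], one row per patch).
#' @param n_boot Bootstrap resamples for the 95\% confidence intervals.
#' @param seed Bootstrap seed.
#' @return An object of class `metric_report`: per-patch table plus means
#'   and percentile-bootstrap CIs on the percent scale.
#' @export
metric_report <- function(per_patch, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("accuracy", "dice", "jaccard") %in% names(per_patch)))
  metrics <- c("accuracy", "dice", "jaccard")
  mean_pct <- vapply(metrics, function(m) 100 * mean(per_patch[[m]]), numeric(1))
  ci <- lapply(seq_along(metrics), function(k)
    100 * bootstrap_ci(per_patch[[metrics[k]]], n_boot, seed + k - 1L))
  names(ci) <- metrics
  structure(list(per_patch = per_patch, mean = mean_pct, ci95 = ci,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d patches (mean, 95%% bootstrap CI):\n",
              nrow(x$per_patch)))
  for (m in names(x$ci95))
    cat(sprintf("  %-9s %5.1f%% (%.1f - %.1f)\n", m, x$mean[[m]],
                x$ci95[[m]]["low"], x$ci95[[m]]["high"]))
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' The CSV holds one row per patch; the JSON summary holds
#' `{metric: {mean, ci_low, ci_high}}` in percent to one decimal.
#'
#' @param report A [metric_report()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the JSON summary list.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_patch, csv_path, row.names = FALSE)
  summary <- lapply(names(report$ci95), function(m)
    list(mean = round(report$mean[[m]], 1),
         ci_low = round(unname(report$ci95[[m]]["low"]), 1),
         ci_high = round(unname(report$ci95[[m]]["high"]), 1)))
  names(summary) <- names(report$ci95)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
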