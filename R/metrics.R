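#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Binary vectors (0/1) of equal length.
#' @return A named integer vector `c(TP, FP, FN, TN)`; dementia (1) is the
#'   positive class.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  c(TP = sum(y_true == 1 & y_pred == 1),
    FP = sum(y_true == 0 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    TN = sum(y_true == 0 & y_pred == 0))
}

#' Threshold metrics from confusion counts
#'
#' Standard definitions: accuracy, F1, precision (PPV), sensitivity
#' (recall), specificity, and negative predictive value. Ratios with a zero
#' denominator are undefined and reported as `NA`, never as 0.
#'
#' @param cm Named counts as returned by [confusion()] (names TP, FP, FN,
#'   TN).
#' @return A named numeric vector with elements `accuracy`, `f1`,
#'   `precision`, `sensitivity`, `specificity`, `npv`.
#' @export
threshold_metrics <- function(cm) {
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  c(accuracy = ratio(tp + tn, tp + fp + fn + tn),
    # 2TP / (2TP + FP + FN): equals the harmonic mean of precision and
    # recall and stays defined when only one of them is
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    precision = prec,
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    npv = ratio(tn, tn + fn))
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney pair statistic: over all
#' (positive, negative) pairs, the fraction ranked correctly, with tied
#' scores counted 1/2.
#'
#' @param y_true Binary labels.
#' @param scores Numeric scores; higher means more positive.
#' @return AUROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # midranks implement the half-credit tie convention
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param y_true Binary labels; `scores` numeric scores.
#' @param scores Numeric scores.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct threshold (descending) plus the (0, 0) origin.
#' @export
roc_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied block
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, if (n0 > 0) fp / n0 else fp * NA),
             tpr = c(0, if (n1 > 0) tp / n1 else tp * NA))
}

#' Precision-recall curve points
#'
#' @param y_true Binary labels; `scores` numeric scores.
#' @param scores Numeric scores.
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y == 1)[keep]
  npred <- seq_along(y)[keep]
  n1 <- sum(y_true == 1)
  data.frame(threshold = s[keep],
             recall = if (n1 > 0) tp / n1 else tp * NA,
             precision = tp / npred)
}

#' Area under the precision-recall curve
#'
#' Step integration (no trapezoids): the sum over descending thresholds of
#' `(recall_i - recall_{i-1}) * precision_i` — the average-precision
#' convention.
#'
#' @param y_true Binary labels; `scores` numeric scores.
#' @param scores Numeric scores.
#' @return AUPRC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auprc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) return(NA_real_)
  pr <- pr_points(y_true, scores)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

nearest_rank <- function(sorted_values, p) {
  n <- length(sorted_values)
  sorted_values[max(1L, ceiling(p * n))]
}

#' Bootstrap confidence intervals for the classifier metric suite
#'
#' Resamples the evaluation set with replacement `n_boot` times (stratified
#' by class by default, so every resample keeps both classes), recomputes
#' every metric per resample, and reports the median and the 2.5th/97.5th
#' percentiles (nearest-rank). The report also carries the point estimates,
#' the confusion matrix at `threshold`, and the ROC/PR curve points.
#'
#' @param y_true Binary labels (dementia = 1); both classes required.
#' @param scores Predicted probabilities/scores.
#' @param n_boot Number of resamples; default 100.
#' @param seed Integer seed.
#' @param threshold Probability cut-off for label metrics; default 0.5.
#' @param stratified Resample within class (default `TRUE`)? When `FALSE`,
#'   resamples that lose a class are skipped and the effective resample
#'   count is reported.
#' @return An object of class `metric_report`: list with `metrics` (data
#'   frame `metric`, `point`, `median`, `lower`, `upper` for AUROC,
#'   accuracy, F1, precision, sensitivity, specificity, NPV), `confusion`,
#'   `roc`, `pr`, `pr_auc`, `n_boot`, `n_boot_effective`, `seed`,
#'   `threshold`.
#' @export
bootstrap_ci <- function(y_true, scores, n_boot = 100, seed = 1,
                         threshold = 0.5, stratified = TRUE) {
  stopifnot(length(y_true) == length(scores))
  if (length(unique(y_true)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  check_range(n_boot, "n_boot", 2, 1e6, integer = TRUE)
  metric_names <- c("auroc", "accuracy", "f1", "precision", "sensitivity",
                    "specificity", "npv")
  eval_once <- function(y, s) {
    cm <- confusion(y, as.numeric(s >= threshold))
    c(auroc = auroc(y, s), threshold_metrics(cm))
  }
  point <- eval_once(y_true, scores)
  idx1 <- which(y_true == 1)
  idx0 <- which(y_true == 0)
  n <- length(y_true)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(metric_names),
                  dimnames = list(NULL, metric_names))
    for (b in seq_len(n_boot)) {
      idx <- if (stratified) {
        c(sample(idx1, length(idx1), replace = TRUE),
          sample(idx0, length(idx0), replace = TRUE))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      if (length(unique(y_true[idx])) < 2L) next  # unstratified: skip
      out[b, ] <- eval_once(y_true[idx], scores[idx])
    }
    out
  })
  effective <- sum(stats::complete.cases(boot[, "auroc"]))
  summarise <- function(v) {
    v <- sort(v[!is.na(v)])
    if (!length(v)) return(c(median = NA_real_, lower = NA_real_,
                             upper = NA_real_))
    c(median = nearest_rank(v, 0.5),
      lower = nearest_rank(v, 0.025),
      upper = nearest_rank(v, 0.975))
  }
  summ <- t(apply(boot, 2, summarise))
  metrics <- data.frame(metric = metric_names,
                        point = unname(point[metric_names]),
                        median = summ[, "median"],
                        lower = summ[, "lower"],
                        upper = summ[, "upper"],
                        row.names = NULL)
  structure(list(metrics = metrics,
                 confusion = confusion(y_true, as.numeric(scores >= threshold)),
                 roc = roc_points(y_true, scores),
                 pr = pr_points(y_true, scores),
                 pr_auc = auprc(y_true, scores),
                 n_boot = n_boot, n_boot_effective = effective,
                 seed = seed, threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metric_report: %d bootstrap resamples, threshold %.2f>\n",
              x$n_boot, x$threshold))
  df <- x$metrics
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("AUPRC (point): %.3f\n", x$pr_auc))
  cat("confusion (TP FP FN TN):", x$confusion, "\n")
  invisible(x)
}
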