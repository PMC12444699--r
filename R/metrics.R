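#' Median absolute percentage error
#'
#' The median over included days of `100 * |point - actual| / actual`.
#' Zero-count days make the percentage error undefined; the default policy
#' excludes them and reports how many were excluded, the alternative
#' `"denominator-max-1"` replaces the denominator by `max(actual, 1)` and
#' keeps every day. With roughly a fifth of admission days at zero this
#' policy choice materially affects the statistic, so it is explicit.
#'
#' @param points numeric forecasts.
#' @param actuals observed counts, same length.
#' @param zero_policy `"exclude-zero-actuals"` (default) or
#'   `"denominator-max-1"`.
#' @return list with `mape` (percent) and `n_excluded`.
#' @export
mape <- function(points, actuals,
                 zero_policy = c("exclude-zero-actuals", "denominator-max-1")) {
  zero_policy <- match.arg(zero_policy)
  if (length(points) != length(actuals)) stop("length mismatch")
  if (length(points) == 0L) stop("no observations")
  if (zero_policy == "exclude-zero-actuals") {
    keep <- actuals != 0
    if (!any(keep)) stop("all days have zero actuals: MAPE undefined under this policy")
    ape <- 100 * abs(points[keep] - actuals[keep]) / actuals[keep]
    list(mape = median(ape), n_excluded = sum(!keep))
  } else {
    ape <- 100 * abs(points - actuals) / pmax(actuals, 1)
    list(mape = median(ape), n_excluded = 0L)
  }
}

#' 95% interval coverage
#'
#' Percentage of days whose interval `[lo, hi]` contains the actual count;
#' endpoints are inclusive.
#'
#' @param lo,hi interval limits, elementwise `lo <= hi`.
#' @param actuals observed counts.
#' @return coverage percentage in `[0, 100]`.
#' @export
interval_coverage <- function(lo, hi, actuals) {
  if (length(lo) != length(hi) || length(lo) != length(actuals))
    stop("length mismatch")
  if (any(lo > hi)) stop("`lo` must be <= `hi` elementwise")
  100 * mean(lo <= actuals & actuals <= hi)
}

#' ROC curve of continuous scores against binary labels
#'
#' Standard empirical ROC: thresholds are the distinct score values in
#' descending order (with a leading `Inf`), a day is called positive when
#' its score is `>=` the threshold; the curve starts at (0, 0) and ends at
#' (1, 1) and both coordinates are non-decreasing.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels logical (or 0/1) labels; both classes must be present.
#' @return an object of class `roc_points`: `thresholds`, `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (all(labels) || !any(labels)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels); n0 <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n0, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("<roc_points> %d thresholds, AUC %.3f\n", length(x$thresholds),
              sum(diff(x$fpr) * (head(x$tpr, -1) + tail(x$tpr, -1)) / 2)))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, with half credit for ties (computed via mid
#' ranks). The confidence interval uses the DeLong placement-variance
#' estimator: `var = var(V10)/n1 + var(V01)/n0` where `V10`/`V01` are the
#' per-observation placements.
#'
#' @param scores numeric scores.
#' @param labels logical labels, both classes present.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci` (length-2, clamped to `[0, 1]`), `se`.
#' @export
auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) stop("both classes must be present")
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ## placements: V10_i = mean_j psi(x_i, y_j), psi = 1 / 0.5 / 0
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r[seq_len(n1)] - rx) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - ry) / n1
  s2 <- var(v10) / n1 + var(v01) / n0
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(s2), 0), 1)
  list(auc = auc, ci = ci, se = sqrt(s2))
}

#' Youden-optimal operating point of an ROC curve
#'
#' Maximizes `J = sensitivity + specificity - 1` over the curve's
#' thresholds; ties are broken by higher sensitivity, then by lower
#' threshold.
#'
#' @param curve a [roc_curve()] result.
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_point <- function(curve) {
  stopifnot(inherits(curve, "roc_points"))
  j <- curve$tpr - curve$fpr
  ord <- order(-j, -curve$tpr, curve$thresholds)
  i <- ord[1L]
  list(threshold = curve$thresholds[i], sensitivity = curve$tpr[i],
       specificity = 1 - curve$fpr[i], j = j[i])
}

#' Confusion-matrix metrics of binary flags against labels
#'
#' Standard 2x2 definitions. Cells with zero denominator (e.g. sensitivity
#' with no positive labels) are reported as `NA`, never silently as 0.
#'
#' @param flags logical predicted flags.
#' @param labels logical observed labels.
#' @return list with `ppv`, `npv`, `sensitivity`, `specificity` and the
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(flags, labels) {
  flags <- as.logical(flags); labels <- as.logical(labels)
  if (length(flags) != length(labels)) stop("length mismatch")
  tp <- sum(flags & labels); fp <- sum(flags & !labels)
  fn <- sum(!flags & labels); tn <- sum(!flags & !labels)
  safe <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Accuracy and discrimination report for a backtest
#'
#' Assembles, per model, the full evaluation row used throughout the
#' package: MAPE (with the zero-day exclusion count), 95% interval
#' coverage, and -- scoring the continuous point forecasts against the
#' observed exceedance labels `actual >= observed_threshold` -- the AUC
#' with DeLong 95% CI, the Youden-optimal sensitivity and specificity, PPV
#' and NPV at the Youden cut, and PPV/NPV/sensitivity/specificity at the
#' 95th-percentile calibrated prediction threshold.
#'
#' @param result a [run_backtest()] result (or any data frame with columns
#'   `model`, `actual`, `point`, `lo95`, `hi95`).
#' @param threshold integer observed high-risk threshold, usually
#'   [observed_threshold()] of the training history.
#' @param percentile calibration percentile for the prediction-side flags.
#' @param zero_policy MAPE zero-day policy, see [mape()].
#' @return a data frame with one row per model.
#' @export
metrics_report <- function(result, threshold, percentile = 0.95,
                           zero_policy = "exclude-zero-actuals") {
  stopifnot(is.numeric(threshold), threshold >= 1)
  rows <- lapply(split(result, result$model), function(d) {
    mp <- mape(d$point, d$actual, zero_policy)
    cov <- interval_coverage(d$lo95, d$hi95, d$actual)
    labels <- d$actual >= threshold
    out <- data.frame(model = d$model[1L], n_days = nrow(d),
                      mape = mp$mape, zero_days_excluded = mp$n_excluded,
                      coverage = cov, auc = NA_real_, auc_lo = NA_real_,
                      auc_hi = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                      cal_threshold = NA_real_, cal_sensitivity = NA_real_,
                      cal_specificity = NA_real_, cal_ppv = NA_real_,
                      cal_npv = NA_real_, stringsAsFactors = FALSE)
    if (any(labels) && !all(labels)) {
      a <- auc_ci(d$point, labels)
      curve <- roc_curve(d$point, labels)
      yp <- youden_point(curve)
      cm <- confusion_metrics(d$point >= yp$threshold, labels)
      out$auc <- a$auc; out$auc_lo <- a$ci[1L]; out$auc_hi <- a$ci[2L]
      out$sensitivity <- yp$sensitivity; out$specificity <- yp$specificity
      out$ppv <- cm$ppv; out$npv <- cm$npv
      if (nrow(d) >= 20L) {
        thr <- prediction_threshold(d$point, percentile)
        cal <- confusion_metrics(classify_days(d$point, thr, strict = TRUE), labels)
        out$cal_threshold <- thr
        out$cal_sensitivity <- cal$sensitivity
        out$cal_specificity <- cal$specificity
        out$cal_ppv <- cal$ppv; out$cal_npv <- cal$npv
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
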