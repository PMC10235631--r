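#' Confusion-matrix metrics
#'
#' Standard binary-classification metrics from the four confusion counts,
#' with the disease class as positive: accuracy, sensitivity (recall of the
#' positive class), specificity, precision, F1, and Matthews correlation.
#' A metric whose denominator is zero is flagged in `flags` and reported
#' as 0.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts (not all zero).
#' @return A `confusion_metrics` list: `tp`, `fp`, `tn`, `fn`, `n`, `acc`,
#'   `sn`, `sp`, `precision`, `f1`, `mcc`, `flags`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("empty evaluation: all counts are zero")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      0
    } else {
      num / den
    }
  }
  acc <- (tp + tn) / n
  sn <- safe(tp, tp + fn, "sn")
  sp <- safe(tn, tn + fp, "sp")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    flags <- c(flags, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = n, acc = acc, sn = sn,
         sp = sp, precision = precision, f1 = f1, mcc = mcc, flags = flags),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> n=%d  acc %.3f  sn %.3f  sp %.3f  prec %.3f  f1 %.3f  mcc %.3f\n",
    x$n, x$acc, x$sn, x$sp, x$precision, x$f1, x$mcc
  ))
  if (length(x$flags)) cat("  undefined (reported as 0):",
                           paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the distinct scores (higher score = more positive),
#' trapezoidal AUC. Tied scores move the curve diagonally, which credits
#' half of each tied pair - identical to the Mann-Whitney rank statistic.
#'
#' @param scores Numeric decision values.
#' @param labels Binary labels; `positive` marks the positive class
#'   (default: `TRUE`/`1`/second factor level).
#' @param positive Positive-class label.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2L) stop("label error: need both classes present")
  if (is.null(positive)) positive <- levels(labels)[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- tapply(p, grp, sum)
  fp <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tp)) / n1
  fpr <- c(0, cumsum(fp)) / n0
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  roc <- data.frame(threshold = c(Inf, s[!duplicated(s)]), fpr = fpr, tpr = tpr)
  list(roc = roc, auc = auc)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the rows of `data` with replacement `n_boot` times (seeded) and
#' returns the `alpha/2` and `1 - alpha/2` percentiles of the metric's
#' bootstrap distribution. Resamples that lose a class (when `data` has a
#' `label` column) are redrawn and counted.
#'
#' @param metric Function `data -> scalar`.
#' @param data Data frame of paired observations (>= 5 rows).
#' @param n_boot Number of resamples (default 1000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)` with attributes `point` (metric on the full
#'   data) and `n_redrawn`.
#' @export
bootstrap_ci <- function(metric, data, n_boot = 1000L, alpha = 0.05, seed = 1L) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 5L) stop("need at least 5 rows")
  set.seed(seed)
  has_label <- "label" %in% names(data)
  vals <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (!has_label || length(unique(data$label[idx])) > 1L) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * n_boot) stop("could not draw non-degenerate resamples")
    }
    vals[b] <- tryCatch(metric(data[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
  }
  if (mean(is.na(vals)) > 0.5) {
    stop("unstable CI: metric undefined on more than half of the resamples")
  }
  ci <- quantile(vals, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  structure(ci, point = metric(data), n_redrawn = redrawn)
}

#' Evaluate a trained classifier on a labeled test set
#'
#' Builds the full evaluation report: confusion counts and metrics at the
#' score threshold 0, the ROC curve and AUC, and percentile-bootstrap 95%
#' confidence intervals for accuracy, sensitivity, specificity, F1 and AUC.
#'
#' @param clf An `osteotex_svm`.
#' @param X Test feature rows (training schema).
#' @param y Test labels.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return An `eval_report`: list with `counts`, `metrics`
#'   ([confusion_metrics()]), `auc`, `roc`, and `ci` (named list of
#'   `c(lo, hi)`).
#' @export
evaluate_classifier <- function(clf, X, y, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(clf, "osteotex_svm"))
  y <- factor(as.character(y), levels = clf$levels)
  if (anyNA(y)) stop("test labels outside the training label set")
  sc <- decision_scores(clf, X)
  pos <- y == clf$positive
  pred_pos <- sc > 0
  cm <- confusion_metrics(
    tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
    tn = sum(!pred_pos & !pos), fn = sum(!pred_pos & pos)
  )
  ra <- roc_auc(sc, y, positive = clf$positive)
  df <- data.frame(score = sc, label = y)
  mk <- function(fun) function(d) fun(d$score, d$label)
  metric_fns <- list(
    acc = mk(function(s, l) mean((s > 0) == (l == clf$positive))),
    sn = mk(function(s, l) {
      p <- l == clf$positive
      if (!any(p)) return(NA_real_)
      mean(s[p] > 0)
    }),
    sp = mk(function(s, l) {
      q <- l != clf$positive
      if (!any(q)) return(NA_real_)
      mean(s[q] <= 0)
    }),
    f1 = mk(function(s, l) {
      p <- l == clf$positive
      tp <- sum(s > 0 & p)
      den <- 2 * tp + sum(s > 0 & !p) + sum(s <= 0 & p)
      if (den == 0) return(NA_real_)
      2 * tp / den
    }),
    auc = mk(function(s, l) roc_auc(s, l, positive = clf$positive)$auc)
  )
  ci <- lapply(seq_along(metric_fns), function(i) {
    bootstrap_ci(metric_fns[[i]], df, n_boot = n_boot, alpha = 0.05,
                 seed = seed + i - 1L)
  })
  names(ci) <- names(metric_fns)
  structure(
    list(counts = c(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn),
         metrics = cm, auc = ra$auc, roc = ra$roc, ci = ci),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("  auc %.3f (95%% CI %.3f-%.3f)\n",
              x$auc, x$ci$auc[1], x$ci$auc[2]))
  invisible(x)
}
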