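#' Confusion counts at a decision threshold
#'
#' Probabilities at or above the threshold are predicted positive (ties
#' resolve to positive).
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return A `confusion_counts` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(probs, labels, threshold = 0.5) {
  if (length(probs) != length(labels)) {
    stop_ppifusion("probs and labels must have equal length",
                   "ppifusion_validation_error")
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop_ppifusion("threshold must be in (0, 1)", "ppifusion_config_error")
  }
  pred <- probs >= threshold
  pos <- labels == 1
  structure(list(tp = sum(pred & pos), tn = sum(!pred & !pos),
                 fp = sum(pred & !pos), fn = sum(!pred & pos)),
            class = "confusion_counts")
}

#' Sensitivity (recall): TP / (TP + FN)
#'
#' Zero denominators return 0 by convention (a logged degenerate case),
#' so fold aggregation never propagates NaN.
#'
#' @param c A [confusion()] result.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) {
    message("sensitivity: no positives in labels; returning 0 by convention")
    return(0)
  }
  c$tp / den
}

#' Precision: TP / (TP + FP)
#' @inheritParams sensitivity
#' @export
precision <- function(c) {
  den <- c$tp + c$fp
  if (den == 0) {
    message("precision: no predicted positives; returning 0 by convention")
    return(0)
  }
  c$tp / den
}

#' F1 score: harmonic mean of precision and sensitivity
#' @inheritParams sensitivity
#' @export
f1_score <- function(c) {
  p <- suppressMessages(precision(c))
  s <- suppressMessages(sensitivity(c))
  if (p + s == 0) return(0)
  2 * p * s / (p + s)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, computed in
#' double precision to avoid integer overflow; any zero factor in the
#' denominator yields 0 by convention.
#'
#' @inheritParams sensitivity
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) {
    message("mcc: degenerate denominator; returning 0 by convention")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive
#' outranks a random negative, with ties counting one half (rank-based,
#' O(n log n)).
#'
#' @param probs Scores.
#' @param labels Binary labels; both classes must be present.
#' @export
auroc <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop_ppifusion("probs and labels must have equal length",
                   "ppifusion_validation_error")
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_ppifusion("AUC undefined: only one class present",
                   "ppifusion_undefined_metric")
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: walking ranks in descending score order
#' (ties broken by stable original order), each positive contributes its
#' precision-at-rank times the recall increment `1/n_pos`. Step
#' interpolation is used rather than trapezoids, which overestimate PR
#' area.
#'
#' @inheritParams auroc
#' @export
aupr <- function(probs, labels) {
  if (length(probs) != length(labels)) {
    stop_ppifusion("probs and labels must have equal length",
                   "ppifusion_validation_error")
  }
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    stop_ppifusion("AUPR undefined: no positives present",
                   "ppifusion_undefined_metric")
  }
  ord <- order(-probs)
  y <- labels[ord]
  tp_cum <- cumsum(y == 1)
  prec_at <- tp_cum / seq_along(y)
  sum(prec_at[y == 1]) / n_pos
}

#' Full metrics report
#'
#' Sensitivity, precision, F1, MCC at the given threshold plus
#' threshold-free AUPR and AUC. When a ranking metric is undefined
#' (single-class input) it is reported as `NA` rather than silently 0.
#'
#' @inheritParams confusion
#' @return A `metrics_report` (named list, includes `counts` and
#'   `threshold`).
#' @export
metrics_report <- function(probs, labels, threshold = 0.5) {
  cc <- confusion(probs, labels, threshold)
  na_if_undefined <- function(expr) {
    tryCatch(expr, ppifusion_undefined_metric = function(e) {
      message(conditionMessage(e)); NA_real_
    })
  }
  structure(list(
    sensitivity = suppressMessages(sensitivity(cc)),
    precision = suppressMessages(precision(cc)),
    f1 = f1_score(cc),
    mcc = suppressMessages(mcc(cc)),
    aupr = na_if_undefined(aupr(probs, labels)),
    auc = na_if_undefined(auroc(probs, labels)),
    threshold = threshold, counts = cc), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report (threshold %.2f): Sen %.1f%%  Pre %.1f%%  F1 %.3f  MCC %.3f  AUPR %.3f  AUC %.3f\n",
    x$threshold, 100 * x$sensitivity, 100 * x$precision, x$f1, x$mcc,
    x$aupr, x$auc))
  invisible(x)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold, suitable
#' for TSV export and plotting.
#'
#' @inheritParams auroc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(probs, labels) {
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  do.call(rbind, lapply(thr, function(t) {
    pred <- probs >= t
    data.frame(threshold = t, fpr = sum(pred & labels == 0) / max(n_neg, 1),
               tpr = sum(pred & labels == 1) / max(n_pos, 1))
  }))
}

#' Precision-recall curve points
#' @inheritParams auroc
#' @return data.frame with `recall`, `precision` in descending-score order.
#' @export
pr_points <- function(probs, labels) {
  ord <- order(-probs)
  y <- labels[ord]
  tp_cum <- cumsum(y == 1)
  data.frame(recall = tp_cum / max(sum(labels == 1), 1),
             precision = tp_cum / seq_along(y))
}

#' Write per-fold and aggregate metrics as TSV
#'
#' One row per fold plus a mean and sd row, with the column set
#' Sen(%), Pre(%), AUPR, AUC, F1, MCC.
#'
#' @param reports List of `metrics_report` objects (one per fold).
#' @param path Output TSV path.
#' @export
write_metrics_tsv <- function(reports, path) {
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(fold = as.character(i), sen_pct = 100 * r$sensitivity,
               pre_pct = 100 * r$precision, aupr = r$aupr, auc = r$auc,
               f1 = r$f1, mcc = r$mcc)
  })
  tab <- do.call(rbind, rows)
  num <- tab[, -1L, drop = FALSE]
  tab <- rbind(tab,
               data.frame(fold = "mean", t(colMeans(num, na.rm = TRUE))),
               data.frame(fold = "sd", t(apply(num, 2L, stats::sd, na.rm = TRUE))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
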