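#' Two-class confusion counts
#'
#' Tabulates true/false positives and negatives with class 1 (minority) as
#' the positive class.
#'
#' @param y true binary labels.
#' @param y_hat predicted binary labels, same length.
#' @return object of class `confusion`: integers `tp`, `fn`, `fp`, `tn`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))  # tp=1 fn=1 fp=1 tn=1
#' @export
confusion <- function(y, y_hat) {
  y <- check_binary_labels(y)
  y_hat <- check_binary_labels(y_hat, "y_hat")
  if (length(y) != length(y_hat)) {
    stop_pgm("label vectors differ in length (%d vs %d)",
             length(y), length(y_hat), class = "pgmelm_shape_error")
  }
  structure(list(tp = sum(y == 1L & y_hat == 1L),
                 fn = sum(y == 1L & y_hat == 0L),
                 fp = sum(y == 0L & y_hat == 1L),
                 tn = sum(y == 0L & y_hat == 0L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d | FP %d  TN %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Imbalance-aware classification metrics from confusion counts
#'
#' Computes the sensitivity/specificity family used for imbalanced two-class
#' problems: TPR (= recall), TNR, precision,
#' \eqn{G\text{-}mean = \sqrt{TPR \cdot TNR}} and the F-measure
#' \eqn{2 \cdot Precision \cdot Recall / (Precision + Recall)}. Ratios with a
#' zero denominator are reported as `NA` (undefined), never silently as 0.
#'
#' @param cm a [confusion] object, or a list with fields `tp`, `fn`, `fp`, `tn`.
#' @return object of class `metrics_report`: `tpr`, `tnr`, `precision`,
#'   `recall`, `g_mean`, `f_measure`.
#' @export
classification_report <- function(cm) {
  tpr <- safe_ratio(cm$tp, cm$tp + cm$fn)
  tnr <- safe_ratio(cm$tn, cm$fp + cm$tn)
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp)
  f <- if (is.na(prec) || is.na(tpr) || (prec + tpr) == 0) NA_real_ else {
    2 * prec * tpr / (prec + tpr)
  }
  g <- if (is.na(tpr) || is.na(tnr)) NA_real_ else sqrt(tpr * tnr)
  structure(list(tpr = tpr, tnr = tnr, precision = prec, recall = tpr,
                 g_mean = g, f_measure = f),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> TPR %.4f  TNR %.4f  Precision %.4f  G-mean %.4f  F-measure %.4f\n",
              x$tpr, x$tnr, x$precision, x$g_mean, x$f_measure))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (plus sentinels) to
#' build the ROC polyline, and integrates it by the trapezoid rule. The
#' resulting AUC equals the probability that a random positive outscores a
#' random negative, ties counting one half.
#'
#' @param scores real-valued classifier scores, larger = more positive.
#' @param y true binary labels; both classes must be present.
#' @return object of class `roc_result`: data frame `roc` with columns
#'   `threshold`, `fpr`, `tpr` (monotone), and scalar `auc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
roc_auc <- function(scores, y) {
  y <- check_binary_labels(y)
  scores <- as.numeric(scores)
  if (length(scores) != length(y)) {
    stop_pgm("scores and labels differ in length", class = "pgmelm_shape_error")
  }
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_pgm("AUC undefined: only one class present",
             class = "pgmelm_single_class")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc> %d points, AUC = %.4f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' Kernel maximum mean discrepancy between two samples
#'
#' Biased (V-statistic) two-sample MMD with a Gaussian kernel
#' \eqn{k(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))}:
#' \eqn{MMD = \sqrt{\overline{k_{XX}} + \overline{k_{YY}} - 2\overline{k_{XY}}}}.
#' Used to score how closely GAN-generated minority samples follow the real
#' minority distribution; identical samples give exactly 0, and lower values
#' mean closer distributions. The default bandwidth is the median pairwise
#' distance over the pooled sample (median heuristic).
#'
#' @param X,Y numeric matrices with the same number of columns, >= 2 rows each.
#' @param bandwidth Gaussian kernel width \eqn{\sigma}; `NULL` (default) for
#'   the median heuristic.
#' @return nonnegative scalar MMD estimate.
#' @export
kernel_mmd <- function(X, Y, bandwidth = NULL) {
  X <- check_matrix(X); Y <- check_matrix(Y)
  if (ncol(X) != ncol(Y)) {
    stop_pgm("samples live in different dimensions (%d vs %d)",
             ncol(X), ncol(Y), class = "pgmelm_shape_error")
  }
  if (nrow(X) < 2 || nrow(Y) < 2) {
    stop_pgm("need at least 2 rows in each sample",
             class = "pgmelm_insufficient_data")
  }
  Zc <- rbind(X, Y)
  D <- as.matrix(stats::dist(Zc))
  if (is.null(bandwidth)) {
    bandwidth <- stats::median(D[upper.tri(D)])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  K <- exp(-D^2 / (2 * bandwidth^2))
  n <- nrow(X); ix <- seq_len(n); iy <- n + seq_len(nrow(Y))
  val <- mean(K[ix, ix]) + mean(K[iy, iy]) - 2 * mean(K[ix, iy])
  sqrt(max(0, val))
}

#' Write a metrics report (plus confusion counts) as JSON
#'
#' @param report a `metrics_report`.
#' @param cm the matching [confusion] object (optional).
#' @param auc optional AUC scalar to include.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, cm = NULL, auc = NULL) {
  out <- unclass(report)
  if (!is.null(auc)) out$auc <- auc
  if (!is.null(cm)) out$confusion <- unclass(cm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
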