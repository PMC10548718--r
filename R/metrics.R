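#' Confusion counts at a threshold
#'
#' Positive calls follow the strict rule `prob > threshold`.
#'
#' @param labels 0/1 vector of true labels.
#' @param probs Predicted probabilities, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, probs, threshold = 0.5) {
  if (length(labels) != length(probs)) {
    stop("labels and probs must have the same length")
  }
  call_pos <- probs > threshold
  c(
    TP = sum(call_pos & labels == 1L),
    TN = sum(!call_pos & labels == 0L),
    FP = sum(call_pos & labels == 0L),
    FN = sum(!call_pos & labels == 1L)
  )
}

# ROC area by trapezoid over the exact step curve; equals the
# Mann-Whitney statistic (concordant pairs + half ties) / (n1 * n0).
.auc_roc <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probs[ord]
  keep <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

# precision-recall area with step interpolation: sum over descending
# score thresholds of (delta recall) * precision.
.auc_pr <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probs[ord]
  keep <- !duplicated(sc, fromLast = TRUE)
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  n1 <- sum(labels == 1L)
  rec <- tp / n1
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Binary-classifier metric report
#'
#' Computes accuracy, area under the ROC curve (true-positive rate
#' against false-positive rate, trapezoid over the exact step curve),
#' area under the precision-recall curve (step interpolation over all
#' distinct scores), Brier score (mean squared difference between the
#' predicted probability and the 0/1 outcome), Matthews correlation
#' coefficient and F1. F1 defaults to the harmonic mean
#' `2PR / (P + R)`; `f1_variant = "half_harmonic"` selects the variant
#' `PR / (P + R)`.
#'
#' With a single-class input the threshold metrics are still returned but
#' the AUCs and MCC are undefined and set to `NA` with a warning.
#'
#' @param labels 0/1 vector of true labels.
#' @param probs Predicted probabilities.
#' @param threshold Decision threshold for ACC/MCC/F1 (default 0.5,
#'   strict).
#' @param f1_variant `"harmonic"` (standard) or `"half_harmonic"`.
#' @return list of class `metric_report` with `acc`, `auc_roc`, `auc_pr`,
#'   `brier`, `mcc`, `f1`, `n`.
#' @export
metrics <- function(labels, probs, threshold = 0.5,
                    f1_variant = c("harmonic", "half_harmonic")) {
  f1_variant <- match.arg(f1_variant)
  if (length(labels) != length(probs)) {
    stop("labels and probs must have the same length")
  }
  cm <- confusion(labels, probs, threshold)
  n <- length(labels)
  acc <- if (n) unname((cm["TP"] + cm["TN"]) / n) else NA_real_
  brier <- if (n) mean((labels - probs)^2) else NA_real_
  both <- length(unique(labels)) == 2L
  if (!both) {
    warning("single-class input: AUC-ROC, AUC-PR and MCC are undefined")
    auc <- aup <- mcc <- NA_real_
  } else {
    auc <- .auc_roc(labels, probs)
    aup <- .auc_pr(labels, probs)
    num <- as.numeric(cm["TP"]) * cm["TN"] - as.numeric(cm["FP"]) * cm["FN"]
    den <- sqrt(as.numeric(cm["TP"] + cm["FP"])) *
      sqrt(as.numeric(cm["TP"] + cm["FN"])) *
      sqrt(as.numeric(cm["TN"] + cm["FP"])) *
      sqrt(as.numeric(cm["TN"] + cm["FN"]))
    mcc <- if (den == 0) 0 else num / den
  }
  pr_den <- cm["TP"] + cm["FP"]
  rc_den <- cm["TP"] + cm["FN"]
  prec <- if (pr_den == 0) 0 else unname(cm["TP"] / pr_den)
  rec <- if (rc_den == 0) 0 else unname(cm["TP"] / rc_den)
  f1 <- if (prec + rec == 0) {
    0
  } else if (f1_variant == "harmonic") {
    2 * prec * rec / (prec + rec)
  } else {
    prec * rec / (prec + rec)
  }
  structure(
    list(acc = acc, auc_roc = auc, auc_pr = aup, brier = brier,
         mcc = unname(mcc), f1 = f1, n = n),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report n=%d> ACC %.4f | AUC-ROC %.4f | AUC-PR %.4f | BS %.4f | MCC %.4f | F1 %.4f\n",
    x$n, x$acc, x$auc_roc, x$auc_pr, x$brier, x$mcc, x$f1
  ))
  invisible(x)
}

#' Write a metric report as JSON
#'
#' @param report A `metric_report`.
#' @param path Destination file.
#' @return Invisibly, the path.
#' @export
write_metric_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
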