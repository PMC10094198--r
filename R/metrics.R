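#' Per-class classification metrics
#'
#' Evaluation follows the multi-label one-vs-rest convention: each class is
#' scored independently from its own confusion counts, and the headline
#' number is the macro F1 — the unweighted arithmetic mean of per-class F1
#' scores — together with the macro AUC.
#'
#' `f1_score()` is the harmonic mean of precision and recall,
#' \deqn{F1 = 2 \cdot \frac{P \cdot R}{P + R},}
#' defined as 0 when both are 0 (the zero-denominator convention, which
#' matters for rare classes).
#'
#' @param precision,recall fractions in \[0, 1\] (vectorised)
#' @return F1 in \[0, 1\]
#' @export
f1_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]")
  denom <- precision + recall
  ifelse(denom == 0, 0, 2 * precision * recall / denom)
}

#' Confusion counts for multi-label predictions
#'
#' @param pred logical/0-1 matrix, records x classes (binarized predictions)
#' @param truth logical/0-1 matrix of the same shape
#' @return a data.frame of class `confusion_counts` with one row per class:
#'   `tp`, `fp`, `fn`, `tn`
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.matrix(pred) > 0.5
  truth <- as.matrix(truth) > 0.5
  stopifnot(all(dim(pred) == dim(truth)))
  classes <- colnames(truth) %||% paste0("class", seq_len(ncol(truth)))
  out <- data.frame(
    class = classes,
    tp = colSums(pred & truth),
    fp = colSums(pred & !truth),
    fn = colSums(!pred & truth),
    tn = colSums(!pred & !truth),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Precision and recall from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN); both are 0 when their
#' denominator is 0.
#'
#' @param counts a `confusion_counts` data.frame (or any data.frame with
#'   `tp`, `fp`, `fn` columns)
#' @return data.frame with columns `class`, `precision`, `recall`
#' @export
precision_recall <- function(counts) {
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  data.frame(
    class = counts$class,
    precision = safe_div(counts$tp, counts$tp + counts$fp),
    recall = safe_div(counts$tp, counts$tp + counts$fn),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Macro F1: unweighted mean of per-class F1 scores
#' @param per_class_f1 non-empty numeric vector of per-class F1 values
#' @export
macro_f1 <- function(per_class_f1) {
  if (length(per_class_f1) == 0L) stop("macro F1 of an empty class list is undefined")
  mean(per_class_f1)
}

#' Area under the one-vs-rest ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#' This equals the trapezoidal area under the ROC curve.
#'
#' @param scores numeric vector of raw scores (higher = more positive)
#' @param targets logical/0-1 vector of the same length
#' @return AUC in \[0, 1\], or `NA` (with a warning) when only one class is
#'   present among the targets
#' @export
auc_score <- function(scores, targets) {
  targets <- as.logical(targets > 0.5)
  stopifnot(length(scores) == length(targets))
  npos <- sum(targets); nneg <- sum(!targets)
  if (npos == 0L || nneg == 0L) {
    warning("AUC undefined: targets contain a single class; reporting NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[targets]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Full per-class metrics report
#'
#' Binarizes scores at `threshold` for the count-based metrics (precision,
#' recall, F1, per-class accuracy = (TP+TN)/n) and uses the raw scores for
#' AUC.  Classes whose targets contain a single level get `NA` AUC and are
#' excluded from the macro AUC with a warning.
#'
#' @param scores numeric matrix, records x classes (probabilities or logits)
#' @param targets 0-1 matrix of the same shape
#' @param threshold decision threshold for binarization (default 0.5)
#' @return object of class `metrics_report`: data.frame `per_class` with
#'   columns `class`, `auc`, `accuracy`, `precision`, `recall`, `f1`, plus
#'   scalars `macro_f1`, `macro_auc`, `macro_accuracy`, `macro_precision`,
#'   `macro_recall`
#' @export
metrics_report <- function(scores, targets, threshold = 0.5) {
  scores <- as.matrix(scores); targets <- as.matrix(targets)
  stopifnot(all(dim(scores) == dim(targets)))
  counts <- confusion_counts(scores >= threshold, targets)
  pr <- precision_recall(counts)
  n <- nrow(scores)
  auc <- vapply(seq_len(ncol(scores)), function(j) {
    if (sum(targets[, j] > 0.5) %in% c(0L, n)) NA_real_
    else auc_score(scores[, j], targets[, j])
  }, numeric(1))
  if (anyNA(auc))
    warning("AUC undefined for ", sum(is.na(auc)),
            " class(es) with single-level targets; excluded from macro AUC")
  per_class <- data.frame(
    class = counts$class,
    auc = auc,
    accuracy = (counts$tp + counts$tn) / n,
    precision = pr$precision,
    recall = pr$recall,
    f1 = f1_score(pr$precision, pr$recall),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(per_class = per_class,
         macro_f1 = macro_f1(per_class$f1),
         macro_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
         macro_accuracy = mean(per_class$accuracy),
         macro_precision = mean(per_class$precision),
         macro_recall = mean(per_class$recall),
         n = n),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Multi-label classification metrics (", x$n, " records)\n", sep = "")
  tab <- metrics_table(x)
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Metrics report as a table with an AVG row
#'
#' Column order mirrors the benchmark tables: AUC, Accuracy, Precision,
#' Recall, F1, with a final AVG row of unweighted means.
#' @param x a `metrics_report`
#' @export
metrics_table <- function(x) {
  stopifnot(inherits(x, "metrics_report"))
  pc <- x$per_class
  rbind(
    data.frame(class = pc$class, auc = pc$auc, accuracy = pc$accuracy,
               precision = pc$precision, recall = pc$recall, f1 = pc$f1,
               stringsAsFactors = FALSE),
    data.frame(class = "AVG", auc = x$macro_auc, accuracy = x$macro_accuracy,
               precision = x$macro_precision, recall = x$macro_recall,
               f1 = x$macro_f1, stringsAsFactors = FALSE))
}

#' Serialize a metrics report
#' @param x a `metrics_report`
#' @param path output path; `.json` or `.csv` decided by `format`
#' @param format `"json"` or `"csv"`
#' @export
write_metrics <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(per_class = x$per_class, macro_f1 = x$macro_f1,
           macro_auc = x$macro_auc, macro_accuracy = x$macro_accuracy,
           macro_precision = x$macro_precision, macro_recall = x$macro_recall,
           n = x$n),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(metrics_table(x), path, row.names = FALSE)
  }
  invisible(path)
}
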