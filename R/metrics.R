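#' Confusion table
#'
#' k x k integer matrix of counts with rows = true class and columns =
#' predicted class, over the union of observed levels (or `levels` if given).
#'
#' @param truth,pred Vectors of true and predicted class labels.
#' @param levels Optional class label order.
#' @return Matrix of class `confusion_table`.
#' @export
confusion_table <- function(truth, pred, levels = NULL) {
  stopifnot(length(truth) == length(pred))
  if (is.null(levels)) {
    levels <- if (is.factor(truth) || is.factor(pred)) {
      sort(unique(c(levels(truth), levels(pred))))
    } else {
      sort(unique(c(as.character(truth), as.character(pred))))
    }
  }
  ct <- table(
    factor(as.character(truth), levels = levels),
    factor(as.character(pred), levels = levels)
  )
  structure(unclass(ct), class = "confusion_table", dimnames = dimnames(ct))
}

as_confusion <- function(x) {
  if (inherits(x, "confusion_table")) return(x)
  if (is.matrix(x) && nrow(x) == ncol(x)) {
    return(structure(x, class = "confusion_table"))
  }
  stop("expected a confusion_table or square matrix", call. = FALSE)
}

#' Balanced accuracy
#'
#' The mean of per-class recall (`diagonal / row sum`), the headline metric
#' for all tasks in this package: it weighs every class equally regardless of
#' class imbalance, so for a binary task it equals the mean of the accuracy
#' on positives and the accuracy on negatives, and a uniform random predictor
#' over k balanced classes scores 1/k in expectation. Classes with zero
#' support are excluded from the average with a warning.
#'
#' @param x A `confusion_table` (or square count matrix), or a vector of true
#'   labels if `pred` is given.
#' @param pred Predicted labels (when `x` is the truth vector).
#' @return Numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(x, pred = NULL) {
  ct <- if (is.null(pred)) as_confusion(x) else confusion_table(x, pred)
  support <- rowSums(ct)
  if (all(support == 0)) stop("all-zero confusion table", call. = FALSE)
  if (any(support == 0)) {
    warning(
      "excluding zero-support class(es): ",
      paste(rownames(ct)[support == 0], collapse = ", "),
      call. = FALSE
    )
  }
  keep <- support > 0
  mean(diag(as.matrix(ct))[keep] / support[keep])
}

#' Per-class, macro and weighted F1
#'
#' Per-class F1 is `2PR/(P+R)` from the confusion table, with the convention
#' that F1 = 0 when precision + recall = 0 (e.g. a class never predicted).
#' Macro F1 averages classes equally; weighted F1 weights by class support.
#' Zero-support classes are excluded as in [balanced_accuracy()].
#'
#' @inheritParams balanced_accuracy
#' @return List with `per_class` (tibble `class`, `precision`, `recall`,
#'   `f1`, `support`), `macro_f1`, `weighted_f1`.
#' @export
f1_scores <- function(x, pred = NULL) {
  ct <- if (is.null(pred)) as_confusion(x) else confusion_table(x, pred)
  m <- as.matrix(ct)
  support <- rowSums(m)
  if (all(support == 0)) stop("all-zero confusion table", call. = FALSE)
  if (any(support == 0)) {
    warning(
      "excluding zero-support class(es): ",
      paste(rownames(m)[support == 0], collapse = ", "),
      call. = FALSE
    )
  }
  predicted <- colSums(m)
  tp <- diag(m)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  keep <- support > 0
  per_class <- tibble::tibble(
    class = rownames(m) %||% as.character(seq_len(nrow(m))),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1), support = unname(as.numeric(support))
  )[keep, ]
  list(
    per_class = per_class,
    macro_f1 = mean(per_class$f1),
    weighted_f1 = sum(per_class$f1 * per_class$support) / sum(per_class$support)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-sum comparison of two metric samples
#'
#' Reporting utility wrapping the two-sided Wilcoxon rank-sum test, used to
#' compare metric samples across holdouts (e.g. full-dimension vs projected
#' features).
#'
#' @param x,y Numeric metric samples.
#' @return Tibble with `statistic` and `p_value`.
#' @export
compare_metric_samples <- function(x, y) {
  ht <- stats::wilcox.test(x, y, exact = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}
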