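# Classification metrics: accuracy, per-class recall, normalized confusion.

#' Classification accuracy
#'
#' Fraction of samples predicted correctly; in the binary case this is the
#' usual (TP + TN) / (TP + FN + FP + TN).
#'
#' @param true_labels,pred_labels Equal-length label vectors (any atomic
#'   type; compared after coercion to character).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels) || length(true_labels) < 1L) {
    stop("label vectors must have equal length >= 1")
  }
  mean(as.character(true_labels) == as.character(pred_labels))
}

#' Per-class recall
#'
#' TP / (TP + FN) for one class.  A class with no true members has undefined
#' recall: `NaN` is returned with a warning.
#'
#' @inheritParams accuracy
#' @param cls The class of interest.
#' @return Fraction in `[0, 1]`, or `NaN`.
#' @export
recall <- function(true_labels, pred_labels, cls) {
  if (length(true_labels) != length(pred_labels) || length(true_labels) < 1L) {
    stop("label vectors must have equal length >= 1")
  }
  pos <- as.character(true_labels) == as.character(cls)
  if (!any(pos)) {
    warning("class '", cls, "' has no true members; recall is undefined")
    return(NaN)
  }
  mean(as.character(pred_labels)[pos] == as.character(cls))
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes, columns predicted classes; each non-empty row sums
#' to 1, and the diagonal entries are the per-class recalls.
#'
#' @inheritParams accuracy
#' @param classes Class labels fixing the row/column order; defaults to the
#'   sorted union of observed labels.
#' @return `n_classes x n_classes` matrix.
#' @export
confusion_normalized <- function(true_labels, pred_labels, classes = NULL) {
  if (length(true_labels) != length(pred_labels) || length(true_labels) < 1L) {
    stop("label vectors must have equal length >= 1")
  }
  tl <- as.character(true_labels)
  pl <- as.character(pred_labels)
  if (is.null(classes)) classes <- sort(unique(c(tl, pl)))
  classes <- as.character(classes)
  counts <- table(factor(tl, levels = classes), factor(pl, levels = classes))
  m <- unclass(counts)
  rs <- rowSums(m)
  m <- m / ifelse(rs == 0, 1, rs)   # empty rows stay all-zero
  dimnames(m) <- list(true = classes, predicted = classes)
  m
}

per_class_counts <- function(true_labels, pred_labels, classes) {
  tl <- as.character(true_labels)
  pl <- as.character(pred_labels)
  do.call(rbind, lapply(classes, function(k) {
    data.frame(class = k,
               TP = sum(tl == k & pl == k),
               FN = sum(tl == k & pl != k),
               FP = sum(tl != k & pl == k),
               TN = sum(tl != k & pl != k))
  }))
}

#' Build an evaluation report
#'
#' Bundles accuracy, per-class recalls, the row-normalized confusion matrix,
#' per-class TP/FP/TN/FN counts, and (optionally) training curves.
#'
#' @inheritParams confusion_normalized
#' @param history Optional per-epoch data frame from a [cnn_lstm] fit.
#' @param fold Optional fold index label.
#' @return An `eval_report` object.
#' @export
eval_report <- function(true_labels, pred_labels, classes = NULL,
                        history = NULL, fold = NA_integer_) {
  tl <- as.character(true_labels)
  if (is.null(classes)) classes <- sort(unique(c(tl, as.character(pred_labels))))
  classes <- as.character(classes)
  conf <- confusion_normalized(true_labels, pred_labels, classes)
  rec <- vapply(classes, function(k) {
    if (!any(tl == k)) NaN else suppressWarnings(recall(true_labels, pred_labels, k))
  }, numeric(1))
  structure(list(accuracy = accuracy(true_labels, pred_labels),
                 recall = rec, confusion = conf,
                 counts = per_class_counts(true_labels, pred_labels, classes),
                 classes = classes, n = length(tl),
                 history = history, fold = fold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s accuracy %.4f over %d samples\n",
              if (!is.na(x$fold)) sprintf(" fold %d,", x$fold) else "",
              x$accuracy, x$n))
  cat("recall:", paste(sprintf("%s %.3f", names(x$recall), x$recall),
                       collapse = ", "), "\n")
  cat("confusion (rows = true):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Save an evaluation report as JSON (confusion also as CSV)
#'
#' @param report An `eval_report`.
#' @param path JSON output path; the confusion matrix additionally goes to
#'   `<path>.confusion.csv`.
#' @export
write_eval_report <- function(report, path) {
  out <- list(fold = report$fold, n = report$n, accuracy = report$accuracy,
              recall = as.list(report$recall),
              confusion = unclass(report$confusion),
              counts = report$counts)
  if (!is.null(report$history)) out$history <- report$history
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(unclass(report$confusion),
                   paste0(path, ".confusion.csv"))
  invisible(path)
}

#' Average per-fold confusion matrices
#'
#' Element-wise mean of the row-normalized per-fold matrices -- the standard
#' way a cross-validated confusion matrix is reported.
#'
#' @param reports List of `eval_report` objects.
#' @return Matrix of the same shape.
#' @export
average_confusion <- function(reports) {
  stopifnot(length(reports) >= 1L)
  Reduce(`+`, lapply(reports, function(r) r$confusion)) / length(reports)
}
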