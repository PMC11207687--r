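# Connectivity dataset: the stack of PLV matrices the classifier consumes.

#' Stack PLV matrices into a classification dataset
#'
#' @param matrices List of `plv_matrix` objects of one band (or a
#'   `side x side x n` array).
#' @param state Character vector of VIMS states, one per matrix (taken from
#'   matrix attributes when omitted).
#' @param subject,segment Optional per-matrix metadata (same default).
#' @param band Band label.
#' @return A `connectivity_dataset`: list with `x` (array), `state`,
#'   `subject`, `segment`, `band`.
#' @export
connectivity_dataset <- function(matrices, state = NULL, subject = NULL,
                                 segment = NULL, band = NULL) {
  if (is.list(matrices)) {
    grab <- function(field, default) {
      v <- vapply(matrices, function(m) {
        a <- attr(m, field)
        if (is.null(a)) default else as.character(a)
      }, character(1))
      v
    }
    if (is.null(state)) state <- grab("state", NA_character_)
    if (is.null(subject)) subject <- as.integer(grab("subject", NA_character_))
    if (is.null(segment)) segment <- as.integer(grab("segment", NA_character_))
    if (is.null(band)) {
      b <- unique(grab("band", NA_character_))
      band <- if (length(b) == 1L) b else NA_character_
    }
    side <- nrow(matrices[[1]])
    x <- array(unlist(lapply(matrices, unclass)),
               c(side, side, length(matrices)))
  } else {
    x <- matrices
  }
  n <- dim(x)[3]
  stopifnot(length(state) == n)
  structure(list(x = x, state = as.character(state),
                 subject = if (is.null(subject)) rep(NA_integer_, n) else subject,
                 segment = if (is.null(segment)) rep(NA_integer_, n) else segment,
                 band = band),
            class = "connectivity_dataset")
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat(sprintf("<connectivity_dataset> %d matrices (%dx%d), band %s\n",
              dim(x$x)[3], dim(x$x)[1], dim(x$x)[2], x$band))
  print(table(state = x$state))
  invisible(x)
}

#' Class labels for the binary or ternary task
#'
#' Ternary: the three VIMS states.  Binary: rest (`VIMS_0`) versus motion
#' sickness (`VIMS_1` and `VIMS_2` merged).
#'
#' @param dataset A `connectivity_dataset`.
#' @param n_classes 2 or 3.
#' @return Factor of labels.
#' @export
dataset_labels <- function(dataset, n_classes = 3L) {
  if (n_classes == 3L) {
    factor(dataset$state, levels = c("VIMS_0", "VIMS_1", "VIMS_2"))
  } else if (n_classes == 2L) {
    factor(ifelse(dataset$state == "VIMS_0", "rest", "sickness"),
           levels = c("rest", "sickness"))
  } else {
    stop("n_classes must be 2 or 3")
  }
}

#' Stratified or subject-wise cross-validation folds
#'
#' Segment-level assignment stratifies by class, mirroring evaluation on a
#' pooled sample set; `split_by = "subject"` keeps every segment of a
#' subject in one fold, which avoids subject-identity leakage between train
#' and test (the stricter protocol).
#'
#' @param dataset A `connectivity_dataset`.
#' @param folds Number of folds.
#' @param labels Class labels (for stratification).
#' @param split_by `"segment"` or `"subject"`.
#' @return Integer vector of fold assignments in `1..folds`.
#' @export
make_folds <- function(dataset, folds, labels = dataset_labels(dataset),
                       split_by = c("segment", "subject")) {
  split_by <- match.arg(split_by)
  n <- dim(dataset$x)[3]
  fold <- integer(n)
  if (split_by == "segment") {
    for (cl in levels(factor(labels))) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    subjects <- unique(dataset$subject)
    sf <- sample(rep_len(seq_len(folds), length(subjects)))
    fold <- sf[match(dataset$subject, subjects)]
  }
  fold
}

#' k-fold cross-validation of the CNN-LSTM
#'
#' Splits the dataset into `train_cfg$folds` folds, trains one model per
#' fold on the remainder and evaluates on the held-out fold.  Every sample
#' appears in exactly one test fold.
#'
#' @param dataset A `connectivity_dataset`.
#' @param model_cfg A [model_config]; its `n_classes` selects the binary or
#'   ternary task.
#' @param train_cfg A [train_config].
#' @param split_by Fold assignment level (see [make_folds()]).
#' @param verbose Print per-fold progress.
#' @return A `cnn_lstm_cv` object: list with per-fold `reports`
#'   ([eval_report]), `fold` assignments, `mean_accuracy`, `sd_accuracy`,
#'   and the averaged confusion matrix.
#' @export
cross_validate <- function(dataset, model_cfg = model_config(),
                           train_cfg = train_config(),
                           split_by = c("segment", "subject"),
                           verbose = FALSE) {
  split_by <- match.arg(split_by)
  labels <- dataset_labels(dataset, model_cfg$n_classes)
  set.seed(train_cfg$seed)
  fold <- make_folds(dataset, train_cfg$folds, labels, split_by)
  reports <- vector("list", train_cfg$folds)
  for (k in seq_len(train_cfg$folds)) {
    test_idx <- which(fold == k)
    train_idx <- which(fold != k)
    fold_cfg <- train_cfg
    fold_cfg$seed <- as.integer((train_cfg$seed * 131 + k) %% 2147483647)
    fit <- cnn_lstm(dataset$x[, , train_idx, drop = FALSE], labels[train_idx],
                    dataset$x[, , test_idx, drop = FALSE], labels[test_idx],
                    model_cfg, fold_cfg)
    pred <- predict(fit, dataset$x[, , test_idx, drop = FALSE])
    reports[[k]] <- eval_report(labels[test_idx], pred,
                                classes = levels(labels),
                                history = fit$history, fold = k)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.3f (%d epochs)", k,
                      train_cfg$folds, reports[[k]]$accuracy,
                      nrow(fit$history)))
    }
  }
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  structure(list(reports = reports, fold = fold,
                 accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 confusion = average_confusion(reports),
                 seed = train_cfg$seed, split_by = split_by,
                 n_classes = model_cfg$n_classes),
            class = "cnn_lstm_cv")
}

#' @export
print.cnn_lstm_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d classes, split by %s)\n",
              length(x$reports), x$n_classes, x$split_by))
  cat(sprintf("accuracy: %.4f +/- %.4f  (folds: %s)\n", x$mean_accuracy,
              x$sd_accuracy, paste(sprintf("%.3f", x$accuracy),
                                   collapse = ", ")))
  cat("average confusion (rows = true):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
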