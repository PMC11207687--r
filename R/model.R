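# CNN-LSTM classifier: R interface over the compiled engine.

#' Model architecture configuration
#'
#' Defaults reproduce the reference architecture: two convolutional blocks
#' (3x3 kernels, stride 1, padding 1, 2x2 max pooling, dropout 0.5 / 0.3)
#' with 64 and 128 channels, two stacked LSTM layers with 100 and 50 hidden
#' units, and a linear softmax head.  A 52x52 input therefore produces a
#' (64, 26, 26) block-1 and a (128, 13, 13) block-2 feature map, read into
#' the LSTM as 13 row-steps of 128*13 = 1664 features.
#'
#' @param input_side Side of the square input matrix (number of channels).
#' @param conv1_channels,conv2_channels Convolutional channels per block.
#' @param dropout1,dropout2 Dropout rates after each pooling layer, in
#'   `[0, 1)`.
#' @param lstm1_hidden,lstm2_hidden Hidden units of the stacked LSTMs.
#' @param n_classes 2 (rest vs sickness) or 3 (rest / light / heavy).
#' @return A `model_config` object.
#' @export
model_config <- function(input_side = 52L, conv1_channels = 64L,
                         conv2_channels = 128L, dropout1 = 0.5,
                         dropout2 = 0.3, lstm1_hidden = 100L,
                         lstm2_hidden = 50L, n_classes = 3L) {
  stopifnot(input_side > 0, input_side %% 4 == 0,
            conv1_channels > 0, conv2_channels > 0,
            lstm1_hidden > 0, lstm2_hidden > 0,
            dropout1 >= 0, dropout1 < 1, dropout2 >= 0, dropout2 < 1,
            n_classes %in% c(2L, 3L))
  structure(list(input_side = as.integer(input_side),
                 conv1_channels = as.integer(conv1_channels),
                 conv2_channels = as.integer(conv2_channels),
                 kernel = 3L, stride = 1L, padding = 1L, pool = 2L,
                 dropout1 = dropout1, dropout2 = dropout2,
                 lstm1_hidden = as.integer(lstm1_hidden),
                 lstm2_hidden = as.integer(lstm2_hidden),
                 n_classes = as.integer(n_classes)),
            class = "model_config")
}

#' Training configuration
#'
#' Adam with learning rate 1e-3, cross-entropy loss, at most 50 epochs with
#' batch size 32, early stopping when the validation loss has not improved
#' for 10 consecutive epochs, 5-fold cross-validation.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch budget per fold.
#' @param batch_size Minibatch size.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping; must be below `max_epochs`.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed RNG seed recorded in every report.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 50L,
                         batch_size = 32L, early_stop_patience = 10L,
                         folds = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1,
            early_stop_patience >= 1, early_stop_patience < max_epochs,
            folds >= 2)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 loss = "cross-entropy", max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "train_config")
}

#' One LSTM cell update (reference implementation)
#'
#' The gate equations in plain R, exported both as documentation of the
#' recurrence and as an independent check of the compiled training engine:
#' forget gate `f = sigmoid(Wfh h + Wfx x + bf)`, input gate `i`, output
#' gate `o` analogous, candidate `g = tanh(Wgh h + Wgx x + bg)`, then
#' `c = f * c_prev + i * g` and `h = o * tanh(c)`.
#'
#' @param gates List with elements `Wfx, Wfh, bf, Wix, Wih, bi, Wox, Woh,
#'   bo, Wgx, Wgh, bg`.
#' @param x_t Input vector at time t.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @return List with `h` and `c`.
#' @examples
#' H <- 3; Fi <- 2
#' z <- function(r, c) matrix(0, r, c)
#' g <- list(Wfx = z(H, Fi), Wfh = z(H, H), bf = numeric(H),
#'           Wix = z(H, Fi), Wih = z(H, H), bi = numeric(H),
#'           Wox = z(H, Fi), Woh = z(H, H), bo = numeric(H),
#'           Wgx = z(H, Fi), Wgh = z(H, H), bg = numeric(H))
#' lstm_step(g, rnorm(Fi), rnorm(H), rnorm(H))$h  # all zero
#' @export
lstm_step <- function(gates, x_t, h_prev, c_prev) {
  sig <- function(z) 1 / (1 + exp(-z))
  f <- sig(gates$Wfh %*% h_prev + gates$Wfx %*% x_t + gates$bf)
  i <- sig(gates$Wih %*% h_prev + gates$Wix %*% x_t + gates$bi)
  o <- sig(gates$Woh %*% h_prev + gates$Wox %*% x_t + gates$bo)
  g <- tanh(gates$Wgh %*% h_prev + gates$Wgx %*% x_t + gates$bg)
  c_t <- f * c_prev + i * g
  list(h = drop(o * tanh(c_t)), c = drop(c_t))
}

# Kaiming / uniform initialization for all parameter tensors
init_weights <- function(cfg) {
  he <- function(r, c, fan) matrix(stats::rnorm(r * c, sd = sqrt(2 / fan)), r, c)
  uni <- function(r, c, fan) {
    lim <- 1 / sqrt(fan)
    matrix(stats::runif(r * c, -lim, lim), r, c)
  }
  f_in <- cfg$conv2_channels * (cfg$input_side %/% 4L)
  lstm_bias <- function(h) {
    b <- matrix(0, 4 * h, 1)
    b[seq_len(h), 1] <- 1          # forget-gate bias 1: remember by default
    b
  }
  list(
    conv1_w = he(cfg$conv1_channels, 9L, 9),
    conv1_b = matrix(0, cfg$conv1_channels, 1),
    bn1_gamma = matrix(1, cfg$conv1_channels, 1),
    bn1_beta = matrix(0, cfg$conv1_channels, 1),
    conv2_w = he(cfg$conv2_channels, cfg$conv1_channels * 9L,
                 cfg$conv1_channels * 9),
    conv2_b = matrix(0, cfg$conv2_channels, 1),
    bn2_gamma = matrix(1, cfg$conv2_channels, 1),
    bn2_beta = matrix(0, cfg$conv2_channels, 1),
    lstm1_wx = uni(4L * cfg$lstm1_hidden, f_in, f_in),
    lstm1_wh = uni(4L * cfg$lstm1_hidden, cfg$lstm1_hidden, cfg$lstm1_hidden),
    lstm1_b = lstm_bias(cfg$lstm1_hidden),
    lstm2_wx = uni(4L * cfg$lstm2_hidden, cfg$lstm1_hidden, cfg$lstm1_hidden),
    lstm2_wh = uni(4L * cfg$lstm2_hidden, cfg$lstm2_hidden, cfg$lstm2_hidden),
    lstm2_b = lstm_bias(cfg$lstm2_hidden),
    fc_w = uni(cfg$n_classes, cfg$lstm2_hidden, cfg$lstm2_hidden),
    fc_b = matrix(0, cfg$n_classes, 1))
}

new_engine <- function(cfg, weights = NULL, double_precision = FALSE) {
  ptr <- cnn_new(cfg$input_side, cfg$conv1_channels, cfg$conv2_channels,
                 cfg$lstm1_hidden, cfg$lstm2_hidden, cfg$n_classes,
                 cfg$dropout1, cfg$dropout2, double_precision)
  if (!is.null(weights)) cnn_set_weights(ptr, weights)
  ptr
}

check_input_array <- function(x, side) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[1] != side || dim(x)[2] != side) {
    stop("input must be ", side, "x", side,
         " matrices (got ", paste(dim(x), collapse = "x"), ")")
  }
  x
}

#' First epoch at which early stopping triggers
#'
#' Training stops after the validation loss has failed to improve on its
#' running best for `patience` consecutive epochs.  Exposed as a pure
#' function of the loss sequence so the stopping rule itself is testable.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Allowed consecutive non-improving epochs.
#' @return The 1-based epoch index after which training stops, or
#'   `length(val_losses)` if the rule never triggers.
#' @examples
#' early_stop_epoch(c(1, 0.5, 0.6, 0.7), patience = 1)  # stops at epoch 3
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  length(val_losses)
}

#' Fit the CNN-LSTM classifier on one train/validation split
#'
#' Trains with Adam and cross-entropy on minibatches, evaluates the
#' validation set after every epoch, stops early by the patience rule and
#' restores the weights of the best-validation-loss epoch.
#'
#' @param x Training inputs: `side x side x n` array of connectivity
#'   matrices (values in `[0, 1]`; fed raw, no further normalization).
#' @param y Integer class labels in `0..n_classes-1` (or a factor).
#' @param val_x,val_y Validation split, disjoint from the training data.
#' @param model_cfg A [model_config].
#' @param train_cfg A [train_config]; its `seed` drives initialization,
#'   shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return A `cnn_lstm` object with elements `weights`, `history` (per-epoch
#'   train/val loss and accuracy), `best_epoch`, `stopped_epoch`, `classes`,
#'   and the two configs.
#' @seealso [predict.cnn_lstm()], [cross_validate()]
#' @export
cnn_lstm <- function(x, y, val_x, val_y, model_cfg = model_config(),
                     train_cfg = train_config(), verbose = FALSE) {
  x <- check_input_array(x, model_cfg$input_side)
  val_x <- check_input_array(val_x, model_cfg$input_side)
  classes <- levels(factor(c(as.character(y), as.character(val_y))))
  y <- as.integer(factor(as.character(y), levels = classes)) - 1L
  val_y <- as.integer(factor(as.character(val_y), levels = classes)) - 1L
  n <- dim(x)[3]
  if (n == 0L || dim(val_x)[3] == 0L) stop("empty training or validation set")
  if (length(y) != n) stop("x and y lengths differ")
  if (length(classes) > model_cfg$n_classes) {
    stop("found ", length(classes), " classes but n_classes = ",
         model_cfg$n_classes)
  }
  present <- sort(unique(y))
  if (length(present) < model_cfg$n_classes) {
    warning("training set contains only ", length(present), " of ",
            model_cfg$n_classes, " classes")
  }

  set.seed(train_cfg$seed)
  ptr <- new_engine(model_cfg, init_weights(model_cfg))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best_loss <- Inf
  best_weights <- NULL
  best_epoch <- 0L
  wait <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    perm <- sample.int(n) - 1L
    tr <- cnn_train_epoch(ptr, x, y, perm, train_cfg$batch_size,
                          train_cfg$learning_rate, TRUE)
    ev <- cnn_eval(ptr, val_x, val_y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr$loss, train_acc = tr$accuracy,
      val_loss = ev$loss, val_acc = ev$accuracy))
    if (verbose) {
      message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, tr$loss, tr$accuracy, ev$loss, ev$accuracy))
    }
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_weights <- cnn_get_weights(ptr)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$early_stop_patience) break
    }
  }
  structure(list(weights = best_weights, history = history,
                 best_epoch = best_epoch, stopped_epoch = epoch,
                 classes = classes, model_config = model_cfg,
                 train_config = train_cfg),
            class = "cnn_lstm")
}

#' Predict VIMS state probabilities or classes
#'
#' @param object A fitted `cnn_lstm`.
#' @param newdata `side x side x n` array (or one matrix).
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or an `n x n_classes` probability
#'   matrix whose rows sum to 1.
#' @export
predict.cnn_lstm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- check_input_array(newdata, object$model_config$input_side)
  ptr <- new_engine(object$model_config, object$weights)
  probs <- cnn_predict_probs(ptr, x)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' @export
print.cnn_lstm <- function(x, ...) {
  cfg <- x$model_config
  cat(sprintf("CNN-LSTM classifier (%d classes: %s)\n", cfg$n_classes,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("conv %d->%d, lstm %d->%d, input %dx%d\n", cfg$conv1_channels,
              cfg$conv2_channels, cfg$lstm1_hidden, cfg$lstm2_hidden,
              cfg$input_side, cfg$input_side))
  h <- x$history
  cat(sprintf("trained %d epochs (best %d): val loss %.4f, val accuracy %.3f\n",
              nrow(h), x$best_epoch, h$val_loss[x$best_epoch],
              h$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.cnn_lstm <- function(object, ...) {
  n_par <- sum(vapply(object$weights[1:16], length, numeric(1)))
  out <- list(model = object$model_config, train = object$train_config,
              n_parameters = n_par, history = object$history,
              best_epoch = object$best_epoch)
  class(out) <- "summary.cnn_lstm"
  out
}

#' @export
print.summary.cnn_lstm <- function(x, ...) {
  cat(sprintf("CNN-LSTM with %s trainable parameters\n",
              format(x$n_parameters, big.mark = ",")))
  print(utils::tail(x$history, 5))
  invisible(x)
}

#' @export
coef.cnn_lstm <- function(object, ...) object$weights

#' Plot training curves
#'
#' Loss and accuracy per epoch for the training and validation sets.
#'
#' @param x A fitted `cnn_lstm`.
#' @param ... Passed to `matplot`.
#' @export
plot.cnn_lstm <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
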