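# CNN-LSTM architecture, gradients, training and cross-validation.

# symmetric unit-diagonal pseudo-connectivity matrices around a base level
toy_matrices <- function(n, base, sd = 0.08) {
  x <- array(0, c(52, 52, n))
  for (i in seq_len(n)) {
    m <- matrix(pmin(pmax(base + rnorm(52 * 52, sd = sd), 0), 1), 52)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    x[, , i] <- m
  }
  x
}

test_that("configs validate their fields", {
  expect_error(model_config(dropout1 = 1), "dropout1")
  expect_error(model_config(n_classes = 4), "n_classes")
  expect_error(train_config(early_stop_patience = 50, max_epochs = 50),
               "patience")
  expect_error(train_config(folds = 1), "folds")
  expect_equal(model_config()$conv1_channels, 64L)
  expect_equal(train_config()$learning_rate, 1e-3)
  expect_equal(train_config()$batch_size, 32L)
})

test_that("a 52x52 input flows through (64,26,26) and (128,13,13) to a simplex", {
  set.seed(70)
  mc <- model_config(n_classes = 3)
  ptr <- vimsnet:::new_engine(mc, vimsnet:::init_weights(mc))
  dbg <- vimsnet:::cnn_forward_debug(ptr, matrix(runif(52 * 52), 52))
  expect_equal(dbg$block1_shape, c(64L, 26L, 26L))
  expect_equal(dbg$block2_shape, c(128L, 13L, 13L))
  expect_equal(dbg$lstm_steps, 13L)
  expect_equal(dbg$lstm_features, 128L * 13L)
  expect_equal(sum(dbg$probs), 1, tolerance = 1e-6)
  expect_true(all(dbg$probs >= 0))
})

test_that("softmax outputs sum to one across random weights and inputs", {
  set.seed(71)
  for (ncls in c(2L, 3L)) {
    mc <- model_config(n_classes = ncls)
    ptr <- vimsnet:::new_engine(mc, vimsnet:::init_weights(mc))
    probs <- vimsnet:::cnn_predict_probs(ptr, array(runif(52 * 52 * 3),
                                                    c(52, 52, 3)))
    expect_equal(dim(probs), c(3L, as.integer(ncls)))
    expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("evaluation-mode forward passes are deterministic", {
  set.seed(72)
  mc <- model_config(n_classes = 3)
  ptr <- vimsnet:::new_engine(mc, vimsnet:::init_weights(mc))
  x <- array(runif(52 * 52 * 2), c(52, 52, 2))
  expect_identical(vimsnet:::cnn_predict_probs(ptr, x),
                   vimsnet:::cnn_predict_probs(ptr, x))
})

test_that("wrong input shapes are rejected with the expected size", {
  set.seed(73)
  mc <- model_config()
  x <- toy_matrices(4, 0.5)
  fit <- structure(list(model_config = mc), class = "cnn_lstm")
  expect_error(predict(fit, array(0, c(40, 40, 2))), "52x52")
})

test_that("lstm_step reproduces the gate equations", {
  H <- 4; Fi <- 3
  z <- function(r, c) matrix(0, r, c)
  zero_gates <- list(Wfx = z(H, Fi), Wfh = z(H, H), bf = numeric(H),
                     Wix = z(H, Fi), Wih = z(H, H), bi = numeric(H),
                     Wox = z(H, Fi), Woh = z(H, H), bo = numeric(H),
                     Wgx = z(H, Fi), Wgh = z(H, H), bg = numeric(H))
  # all-zero parameters from a zero cell state: gates at 0.5, candidate
  # tanh(0) = 0, so c = 0 and h = 0.5 * tanh(0) = 0
  out <- lstm_step(zero_gates, rnorm(Fi), rnorm(H), numeric(H))
  expect_equal(out$h, rep(0, H))
  expect_equal(out$c, rep(0, H))
  # saturated forget gate with input gate forced shut: perfect memory
  mem <- zero_gates
  mem$bf <- rep(1e3, H)
  mem$bi <- rep(-1e3, H)
  c_prev <- rnorm(H)
  expect_equal(lstm_step(mem, rnorm(Fi), rnorm(H), c_prev)$c, c_prev)

  # random instance against an independently coded gate computation
  set.seed(74)
  g <- lapply(zero_gates, function(m) {
    if (is.matrix(m)) matrix(rnorm(length(m), sd = 0.5), nrow(m))
    else rnorm(length(m), sd = 0.5)
  })
  x_t <- rnorm(Fi); h0 <- rnorm(H); c0 <- rnorm(H)
  out <- lstm_step(g, x_t, h0, c0)
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(g$Wfh %*% h0 + g$Wfx %*% x_t + g$bf)
  i <- sig(g$Wih %*% h0 + g$Wix %*% x_t + g$bi)
  o <- sig(g$Woh %*% h0 + g$Wox %*% x_t + g$bo)
  cc <- f * c0 + i * tanh(g$Wgh %*% h0 + g$Wgx %*% x_t + g$bg)
  expect_equal(out$c, drop(cc), tolerance = 1e-10)
  expect_equal(out$h, drop(o * tanh(cc)), tolerance = 1e-10)
})

test_that("the engine's LSTM agrees with the R reference implementation", {
  # feed a known sequence through a double-precision engine whose conv part
  # is bypassed analytically is impractical; instead check the exported
  # weights' gate layout by replaying the recurrence in R on the block-2
  # sequence is covered by the gradient test; here we verify shape contracts
  w <- vimsnet:::init_weights(model_config())
  expect_equal(dim(w$lstm1_wx), c(400L, 1664L))
  expect_equal(dim(w$lstm2_wx), c(200L, 100L))
  expect_equal(w$lstm1_b[1:100, 1], rep(1, 100))  # forget bias
})

test_that("analytic gradients match central finite differences", {
  set.seed(75)
  mc <- model_config(n_classes = 3)
  w <- vimsnet:::init_weights(mc)
  ptr <- vimsnet:::new_engine(mc, w, double_precision = TRUE)
  x <- array(runif(52 * 52 * 3), c(52, 52, 3))
  y <- c(0L, 1L, 2L)
  vimsnet:::cnn_loss_grad(ptr, x, y)
  gr <- vimsnet:::cnn_get_grads(ptr)
  h <- 1e-5
  rel <- c()
  for (nm in names(gr)) {
    for (rep in 1:2) {
      i <- sample(length(w[[nm]]), 1)
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + h
      l1 <- vimsnet:::cnn_loss_only(
        vimsnet:::new_engine(mc, wp, double_precision = TRUE), x, y)
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - h
      l2 <- vimsnet:::cnn_loss_only(
        vimsnet:::new_engine(mc, wm, double_precision = TRUE), x, y)
      num <- (l1 - l2) / (2 * h)
      rel <- c(rel, abs(num - gr[[nm]][i]) /
                 max(abs(num), abs(gr[[nm]][i]), 1e-8))
    }
  }
  # finite differences are noisy near ReLU/max-pool kinks; the bulk of the
  # comparisons must agree tightly and none may disagree grossly
  expect_lt(median(rel), 1e-5)
  expect_lt(max(rel), 0.05)
})

test_that("the early-stopping rule triggers at the first patience breach", {
  expect_equal(early_stop_epoch(c(1, 0.5, 0.6, 0.7), patience = 1), 3)
  expect_equal(early_stop_epoch(c(1, 0.9, 0.8, 0.7), patience = 2), 4)
  expect_equal(early_stop_epoch(c(1, 1.1, 1.2, 1.3), patience = 2), 3)
  expect_equal(early_stop_epoch(c(5, 4, 4.5, 3, 3.5, 3.6, 3.7), patience = 3),
               7)
})

test_that("training stops early on a rising validation loss (patience 1)", {
  set.seed(76)
  x <- toy_matrices(24, 0.5)
  y <- rep(0:1, 12)
  # validation labels opposite to training: val loss rises as training fits
  fit <- cnn_lstm(x[, , 1:16], y[1:16], x[, , 17:24], 1 - y[17:24],
                  model_config(n_classes = 2),
                  train_config(max_epochs = 10, early_stop_patience = 1,
                               seed = 3))
  expect_lte(fit$stopped_epoch, nrow(fit$history))
  expect_lt(fit$stopped_epoch, 10)
  expect_equal(fit$stopped_epoch,
               early_stop_epoch(fit$history$val_loss, 1))
  # restored weights correspond to the best validation epoch
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("the optimizer reduces training loss on a single batch", {
  set.seed(77)
  x <- toy_matrices(16, 0.4)
  y <- rep(0:1, 8)
  fit <- cnn_lstm(x, y, x, y, model_config(n_classes = 2),
                  train_config(max_epochs = 6, early_stop_patience = 5,
                               batch_size = 16, seed = 4))
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
})

test_that("linearly separable coupling classes are learned almost perfectly", {
  set.seed(78)
  n <- 60
  x <- array(0, c(52, 52, 2 * n))
  x[, , 1:n] <- toy_matrices(n, 0.25)
  x[, , (n + 1):(2 * n)] <- toy_matrices(n, 0.6)
  y <- rep(0:1, each = n)
  idx <- sample(2 * n)
  x <- x[, , idx]
  y <- y[idx]
  tr <- 1:90
  va <- 91:120
  fit <- cnn_lstm(x[, , tr], y[tr], x[, , va], y[va],
                  model_config(n_classes = 2),
                  train_config(max_epochs = 10, early_stop_patience = 3,
                               seed = 5))
  expect_gte(max(fit$history$val_acc), 0.95)
  pred <- predict(fit, x[, , va])
  expect_gte(accuracy(y[va], as.integer(as.character(pred))), 0.95)
  probs <- predict(fit, x[, , va], type = "prob")
  expect_equal(rowSums(probs), rep(1, length(va)), tolerance = 1e-6)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(79)
  x <- toy_matrices(24, 0.5)
  y <- rep(0:1, 12)
  cfg <- train_config(max_epochs = 3, early_stop_patience = 2, seed = 11)
  f1 <- cnn_lstm(x[, , 1:16], y[1:16], x[, , 17:24], y[17:24],
                 model_config(n_classes = 2), cfg)
  f2 <- cnn_lstm(x[, , 1:16], y[1:16], x[, , 17:24], y[17:24],
                 model_config(n_classes = 2), cfg)
  expect_equal(f1$history$train_loss, f2$history$train_loss,
               tolerance = 1e-6)
  expect_equal(f1$history$val_loss, f2$history$val_loss, tolerance = 1e-6)
})

test_that("a class missing from the training set warns", {
  set.seed(80)
  x <- toy_matrices(12, 0.5)
  expect_warning(
    cnn_lstm(x[, , 1:8], rep(0L, 8), x[, , 9:12], rep(c(0L, 1L), 2),
             model_config(n_classes = 2),
             train_config(max_epochs = 2, early_stop_patience = 1)),
    "classes")
  expect_error(
    cnn_lstm(x[, , 0], integer(0), x, rep(0L, 12), model_config(),
             train_config()),
    "empty")
})

test_that("cross-validation folds partition the dataset with stratification", {
  set.seed(81)
  n <- 100
  ds <- connectivity_dataset(array(runif(52 * 52 * n), c(52, 52, n)),
                             state = rep(c("VIMS_0", "VIMS_1", "VIMS_2"),
                                         length.out = n),
                             subject = rep(1:10, each = 10), band = "gamma")
  fold <- make_folds(ds, 5, dataset_labels(ds))
  expect_equal(sort(unique(fold)), 1:5)
  # 100 samples in 5 stratified folds: 20 +/- rounding within classes
  expect_true(all(abs(table(fold) - 20) <= 2))
  # union of test folds is the dataset, each sample exactly once
  expect_equal(sort(unlist(lapply(1:5, function(k) which(fold == k)))),
               seq_len(n))
  # subject-level folds keep subjects intact
  fold_s <- make_folds(ds, 5, split_by = "subject")
  for (s in unique(ds$subject)) {
    expect_length(unique(fold_s[ds$subject == s]), 1L)
  }
  # fold sizes for the canonical 1500-sample set are 300
  expect_equal(table(rep_len(1:5, 1500))[[1]], 300)
})

test_that("binary labels merge the two sickness states", {
  ds <- connectivity_dataset(array(0, c(4, 4, 6)),
                             state = rep(c("VIMS_0", "VIMS_1", "VIMS_2"), 2))
  l3 <- dataset_labels(ds, 3)
  l2 <- dataset_labels(ds, 2)
  expect_equal(levels(l3), c("VIMS_0", "VIMS_1", "VIMS_2"))
  expect_equal(as.character(l2),
               rep(c("rest", "sickness", "sickness"), 2))
})
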