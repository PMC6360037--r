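test_that("the cross-entropy matches its closed forms", {
  one_hot <- function(y) { Y <- matrix(0, length(y), 4); Y[cbind(seq_along(y), y)] <- 1; Y }
  # perfect predictions
  Y <- one_hot(c(1, 2, 3, 4))
  P <- Y * (1 - 3e-12) + 1e-12
  expect_lt(categorical_cross_entropy(Y, P), 1e-11)
  # uniform predictor: ln(4)/4, independent of N
  for (n in c(1L, 7L, 50L)) {
    Yn <- one_hot(rep_len(1:4, n))
    expect_equal(categorical_cross_entropy(Yn, matrix(0.25, n, 4)),
                 log(4) / 4, tolerance = 1e-12)
  }
  # hand-computed double sum, N = 2, M = 4
  Y2 <- one_hot(c(2, 4))
  P2 <- rbind(c(0.1, 0.6, 0.2, 0.1), c(0.25, 0.05, 0.3, 0.4))
  expect_equal(categorical_cross_entropy(Y2, P2),
               -(log(0.6) + log(0.4)) / 8, tolerance = 1e-12)
  # clipping keeps confident-wrong predictions finite
  P3 <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  expect_warning(l <- categorical_cross_entropy(Y2, P3), "clipped")
  expect_true(is.finite(l))
  expect_error(categorical_cross_entropy(P2, P2), "one-hot")
})

test_that("the layer-growth rule generates 32, 64, 128, ...", {
  expect_identical(mlp_layer_growth(0L), integer(0))
  expect_identical(mlp_layer_growth(1L), 32L)
  expect_identical(mlp_layer_growth(4L), c(32L, 64L, 128L, 256L))
  expect_identical(rev(mlp_layer_growth(4L)), c(256L, 128L, 64L, 32L))
})

test_that("MLP parameter counts match the dense-layer arithmetic", {
  m <- build_mlp()
  count <- sum(vapply(m$params, length, 0L))
  # independent closed form: sum over consecutive dims of (in*out + out)
  dims <- c(1620L, 256L, 128L, 64L, 32L, 4L)
  expected <- 0L
  for (l in seq_len(length(dims) - 1L))
    expected <- expected + dims[l] * dims[l + 1L] + dims[l + 1L]
  expect_identical(count, expected)

  m0 <- build_mlp(hidden_sizes = integer(0))   # logistic regression
  expect_identical(sum(vapply(m0$params, length, 0L)), 1620L * 4L + 4L)
})

test_that("network outputs are probability distributions", {
  m <- build_mlp(input_dim = 10L, hidden_sizes = c(8L, 4L), seed = 3L)
  p <- predict(m, matrix(rnorm(50), 5))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p >= 0))

  lm <- build_lstm(input_dim = 6L, seq_len = 10L, units = 8L,
                   fc_sizes = 5L, seed = 3L)
  pl <- predict(lm, array(rnorm(4 * 10 * 6), c(4, 10, 6)))
  expect_equal(rowSums(pl), rep(1, 4), tolerance = 1e-9)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(14)
  one_hot <- gaitdx:::.one_hot
  # MLP
  m <- build_mlp(input_dim = 7L, hidden_sizes = c(5L, 4L),
                 dropout_rate = 0, seed = 2L)
  x <- matrix(rnorm(6 * 7), 6); Y <- one_hot(sample(1:4, 6, TRUE))
  fw <- gaitdx:::.mlp_forward(m$params, x, 2L)
  gr <- gaitdx:::.mlp_backward(m$params, fw, Y, 2L)
  loss_at <- function(p)
    categorical_cross_entropy(Y, gaitdx:::.mlp_forward(p, x, 2L)$probs)
  for (k in names(m$params)) {
    j <- sample(length(m$params[[k]]), 1L)
    p1 <- m$params; p1[[k]][j] <- p1[[k]][j] + 1e-6
    p2 <- m$params; p2[[k]][j] <- p2[[k]][j] - 1e-6
    expect_equal(gr[[k]][j], (loss_at(p1) - loss_at(p2)) / 2e-6,
                 tolerance = 1e-5)
  }
  # LSTM (including backprop through time)
  lm <- build_lstm(input_dim = 5L, seq_len = 4L, units = 6L,
                   fc_sizes = 5L, seed = 4L)
  xa <- array(rnorm(3 * 4 * 5), c(3, 4, 5)); Y <- one_hot(c(1, 3, 4))
  fw <- gaitdx:::.lstm_forward(lm$params, xa, 6L, 1L, keep_cache = TRUE)
  gr <- gaitdx:::.lstm_backward(lm$params, fw, xa, Y, 6L, 1L)
  loss_at <- function(p)
    categorical_cross_entropy(Y, gaitdx:::.lstm_forward(p, xa, 6L, 1L)$probs)
  for (k in names(lm$params)) {
    j <- sample(length(lm$params[[k]]), 1L)
    p1 <- lm$params; p1[[k]][j] <- p1[[k]][j] + 1e-6
    p2 <- lm$params; p2[[k]][j] <- p2[[k]][j] - 1e-6
    expect_equal(gr[[k]][j], (loss_at(p1) - loss_at(p2)) / 2e-6,
                 tolerance = 1e-5)
  }
})

test_that("MLP training stops under the loss threshold on separable data", {
  set.seed(5)
  n <- 120L
  y <- rep_len(1:4, n)
  x <- matrix(rnorm(n * 6, 0, 0.3), n)
  x[, 1] <- x[, 1] + c(0, 4, 0, 4)[y]
  x[, 2] <- x[, 2] + c(0, 0, 4, 4)[y]
  cfg <- train_config(batch_size = 32L, seed = 9L)
  fit <- gait_mlp(x, y, hidden_sizes = c(16L), dropout_rate = 0.2,
                  cfg = cfg)
  expect_lt(utils::tail(fit$loss_trace, 1), 0.10)
  expect_lt(fit$epochs_run, cfg$mlp_max_epochs)
  expect_gt(mean(predict(fit, x, type = "class") == y), 0.95)
})

test_that("the epoch cap is enforced on unlearnable labels", {
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40)
  y <- sample(1:4, 40, TRUE)              # labels independent of features
  cfg <- train_config(batch_size = 20L, mlp_max_epochs = 25L, seed = 2L)
  fit <- gait_mlp(x, y, hidden_sizes = 4L, dropout_rate = 0.5, cfg = cfg)
  expect_identical(fit$epochs_run, 25L)
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  set.seed(7)
  x <- matrix(rnorm(60 * 5), 60); y <- rep_len(1:4, 60)
  cfg <- train_config(batch_size = 25L, mlp_max_epochs = 8L, seed = 31L)
  f1 <- gait_mlp(x, y, hidden_sizes = 8L, cfg = cfg)
  f2 <- gait_mlp(x, y, hidden_sizes = 8L, cfg = cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params, f2$params)

  xa <- array(rnorm(30 * 8 * 4), c(30, 8, 4)); ya <- rep_len(1:4, 30)
  cfgl <- train_config(batch_size = 15L, lstm_epochs = 3L, seed = 13L)
  l1 <- gait_lstm(xa, ya, units = 6L, fc_sizes = 5L, cfg = cfgl)
  l2 <- gait_lstm(xa, ya, units = 6L, fc_sizes = 5L, cfg = cfgl)
  expect_identical(l1$loss_trace, l2$loss_trace)
})

test_that("an untrained LSTM is near-uniform on constant windows", {
  lm <- build_lstm(input_dim = 81L, seq_len = 75L, units = 16L,
                   fc_sizes = c(8L), seed = 21L)
  x <- array(0.5, c(6, 75, 81))
  p <- predict(lm, x)
  expect_lte(max(p), 0.35)
})

test_that("a small LSTM separates mean-level sequence classes", {
  set.seed(8)
  n <- 240L
  y <- rep_len(1:4, n)
  xa <- array(rnorm(n * 12 * 3, 0, 0.5), c(n, 12, 3))
  xa[, , 1] <- xa[, , 1] + c(-3, -1, 1, 3)[y]
  cfg <- train_config(batch_size = 10L, lstm_epochs = 15L, seed = 17L)
  fit <- gait_lstm(xa, y, units = 12L, fc_sizes = 8L, cfg = cfg)
  expect_gt(mean(predict(fit, xa, type = "class") == y), 0.9)
})

test_that("the RBF SVM baseline behaves like a maximum-margin classifier", {
  set.seed(9)
  n <- 100L
  y <- rep(c(1L, 3L), each = n / 2)
  x <- matrix(rnorm(n * 4, 0, 0.5), n)
  x[y == 3L, 1] <- x[y == 3L, 1] + 6
  fit <- gait_svm(x, y)
  expect_identical(predict(fit, x), y)              # separable blobs
  p1 <- predict(gait_svm(x, y), x)
  expect_identical(p1, predict(gait_svm(x, y), x))  # deterministic

  y_shuf <- sample(y)                                # permutation baseline
  acc <- mean(predict(gait_svm(x, y_shuf), x) == y)
  expect_lt(acc, 0.75)
  expect_error(gait_svm(x, rep(2L, n)), "2 classes")
})
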