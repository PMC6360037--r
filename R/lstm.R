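#' Build an (untrained) single-layer LSTM sequence classifier
#'
#' One LSTM layer (tanh cell activation, sigmoid gates) consumes the
#' 75 x 81 angle windows; its final-step hidden state feeds a fully
#' connected ReLU stack and a softmax over the 4 forms, i.e. the network
#' maps a whole sequence to a single prediction. A single recurrent layer
#' is used deliberately: stacking LSTM layers thins the gradient between
#' layers and overfits small clinical datasets.
#'
#' @param input_dim per-frame feature count (81).
#' @param seq_len window length in frames (75).
#' @param units LSTM hidden width; default 128.
#' @param fc_sizes fully connected stack on top; default `c(128, 64, 32)`.
#' @param output_dim number of classes.
#' @param seed seed for weight initialization.
#' @return An object of class `gait_lstm` (untrained).
#' @export
build_lstm <- function(input_dim = 81L, seq_len = 75L, units = 128L,
                       fc_sizes = c(128L, 64L, 32L), output_dim = 4L,
                       seed = 1L) {
  stopifnot(units >= 1L, all(fc_sizes >= 1L))
  set.seed(as.integer(seed))
  u <- as.integer(units)
  params <- list(
    Wx = .glorot(input_dim, 4L * u),
    Wh = .glorot(u, 4L * u),
    b = rep(c(0, 1, 0, 0), each = u)       # forget-gate bias init 1
  )
  dims <- c(u, fc_sizes, output_dim)
  for (l in seq_len(length(dims) - 1L)) {
    params[[paste0("W", l)]] <- .glorot(dims[l], dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  structure(list(params = params, units = u, fc_sizes = as.integer(fc_sizes),
                 input_dim = as.integer(input_dim),
                 seq_len = as.integer(seq_len),
                 output_dim = as.integer(output_dim), trained = FALSE,
                 loss_trace = numeric(0),
                 feature_center = NULL, feature_scale = NULL),
            class = "gait_lstm")
}

# gate order inside the 4u-wide pre-activation: i, f, g, o
.lstm_forward <- function(params, x, units, n_fc, keep_cache = FALSE) {
  n <- dim(x)[1]; Tn <- dim(x)[2]
  u <- units
  H <- matrix(0, n, u); C <- matrix(0, n, u)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    Xt <- x[, t, , drop = TRUE]
    if (n == 1L) Xt <- rbind(Xt)
    Z <- .addb(Xt %*% params$Wx + H %*% params$Wh, params$b)
    gi <- .sigmoid(Z[, 1:u, drop = FALSE])
    gf <- .sigmoid(Z[, u + 1:u, drop = FALSE])
    gg <- tanh(Z[, 2 * u + 1:u, drop = FALSE])
    go <- .sigmoid(Z[, 3 * u + 1:u, drop = FALSE])
    C_prev <- C
    C <- gf * C + gi * gg
    tc <- tanh(C)
    H_prev <- H
    H <- go * tc
    if (keep_cache)
      cache[[t]] <- list(Xt = Xt, H_prev = H_prev, C_prev = C_prev,
                         gi = gi, gf = gf, gg = gg, go = go, tc = tc)
  }
  # fully connected head on the final hidden state
  a <- H
  fc_cache <- list(a0 = H)
  for (l in seq_len(n_fc)) {
    z <- .addb(a %*% params[[paste0("W", l)]], params[[paste0("b", l)]])
    a <- .relu(z)
    fc_cache[[paste0("z", l)]] <- z
    fc_cache[[paste0("a", l)]] <- a
  }
  lo <- n_fc + 1L
  logits <- .addb(a %*% params[[paste0("W", lo)]], params[[paste0("b", lo)]])
  probs <- .softmax(logits)
  list(probs = probs, cache = cache, fc_cache = fc_cache)
}

.lstm_backward <- function(params, fw, x, y_onehot, units, n_fc) {
  n <- nrow(y_onehot); m <- ncol(y_onehot)
  u <- units; Tn <- dim(x)[2]
  grads <- lapply(params, function(p) p * 0)
  # FC head
  delta <- (fw$probs - y_onehot) / (n * m)
  for (l in seq(n_fc + 1L, 1L)) {
    a_prev <- fw$fc_cache[[paste0("a", l - 1L)]] %||% fw$fc_cache$a0
    grads[[paste0("W", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params[[paste0("W", l)]])) *
        (fw$fc_cache[[paste0("z", l - 1L)]] > 0)
    }
  }
  # after the loop, delta holds dL/dz of the first FC layer (or of the
  # logits when n_fc == 0), so the hidden-state gradient is one matmul away
  dH <- delta %*% t(params$W1)
  dC <- matrix(0, n, u)
  for (t in seq(Tn, 1L)) {
    cc <- fw$cache[[t]]
    dgo <- dH * cc$tc
    dC <- dC + dH * cc$go * (1 - cc$tc^2)
    dgi <- dC * cc$gg
    dgg <- dC * cc$gi
    dgf <- dC * cc$C_prev
    dC <- dC * cc$gf
    dZ <- cbind(dgi * cc$gi * (1 - cc$gi),
                dgf * cc$gf * (1 - cc$gf),
                dgg * (1 - cc$gg^2),
                dgo * cc$go * (1 - cc$go))
    grads$Wx <- grads$Wx + crossprod(cc$Xt, dZ)
    grads$Wh <- grads$Wh + crossprod(cc$H_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dH <- dZ %*% t(params$Wh)
  }
  grads
}

#' Train the LSTM sequence classifier
#'
#' Same regime as the MLP (Adam with default parameters, `1/(N*M)`
#' cross-entropy, minibatches of 100 reshuffled each epoch) but trained
#' for a fixed `cfg$lstm_epochs` (15) epochs: the training loss drops
#' below 0.10 well within that budget and longer training overfits.
#' Per-feature standardization (computed on the training windows) is
#' stored on the model.
#'
#' @param model a [build_lstm()] object.
#' @param x `n x seq_len x input_dim` array of windows.
#' @param y integer form labels (1..4).
#' @param cfg a [train_config()].
#' @return The trained `gait_lstm` with `$loss_trace`.
#' @export
train_lstm <- function(model, x, y, cfg = train_config()) {
  stopifnot(inherits(model, "gait_lstm"), dim(x)[1] == length(y))
  if (length(unique(y)) < 2L)
    stop("training set must contain at least 2 classes")
  set.seed(cfg$seed)
  n <- dim(x)[1]
  # per-angle statistics pooled over windows and time
  ctr_d <- apply(x, 3L, mean)
  scl_d <- apply(x, 3L, stats::sd); scl_d[scl_d < 1e-8] <- 1
  xs <- .lstm_standardize(x, ctr_d, scl_d)
  Y <- .one_hot(y, model$output_dim)
  params <- model$params
  opt <- .adam_init(params)
  trace <- numeric(0)
  for (epoch in seq_len(cfg$lstm_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xs[idx, , , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      fw <- .lstm_forward(params, xb, model$units,
                          length(model$fc_sizes), keep_cache = TRUE)
      if (!all(is.finite(fw$probs)))
        stop("non-finite network output at epoch ", epoch)
      gr <- .lstm_backward(params, fw, xb, yb, model$units,
                           length(model$fc_sizes))
      st <- .adam_step(opt, params, gr)
      opt <- st$state; params <- st$params
      epoch_loss <- epoch_loss +
        suppressWarnings(categorical_cross_entropy(yb, fw$probs))
      nb <- nb + 1L
    }
    trace <- c(trace, epoch_loss / nb)
  }
  model$params <- params
  model$trained <- TRUE
  model$loss_trace <- trace
  model$epochs_run <- length(trace)
  model$feature_center <- ctr_d
  model$feature_scale <- scl_d
  model$cfg <- cfg
  model
}

.lstm_standardize <- function(x, ctr, scl) {
  n <- dim(x)[1]; Tn <- dim(x)[2]; d <- dim(x)[3]
  out <- x
  for (k in seq_len(d)) out[, , k] <- (x[, , k] - ctr[k]) / scl[k]
  out
}

#' Fit an LSTM form classifier (build + train front end)
#'
#' @inheritParams train_lstm
#' @inheritParams build_lstm
#' @return A trained `gait_lstm`.
#' @export
gait_lstm <- function(x, y, units = 128L, fc_sizes = c(128L, 64L, 32L),
                      cfg = train_config()) {
  model <- build_lstm(dim(x)[3], dim(x)[2], units, fc_sizes,
                      seed = cfg$seed)
  train_lstm(model, x, y, cfg)
}

#' @export
predict.gait_lstm <- function(object, newdata, type = c("prob", "class"),
                              batch = 512L, ...) {
  type <- match.arg(type)
  x <- newdata
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  if (!is.null(object$feature_center))
    x <- .lstm_standardize(x, object$feature_center, object$feature_scale)
  n <- dim(x)[1]
  probs <- matrix(NA_real_, n, object$output_dim)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    probs[idx, ] <- .lstm_forward(object$params,
                                  x[idx, , , drop = FALSE],
                                  object$units,
                                  length(object$fc_sizes))$probs
  }
  colnames(probs) <- paste0("form", seq_len(object$output_dim))
  if (type == "class") max.col(probs, ties.method = "first") else probs
}

#' @export
print.gait_lstm <- function(x, ...) {
  cat("<gait_lstm> ", x$seq_len, "x", x$input_dim, " -> LSTM(", x$units,
      ", tanh) -> ", paste(x$fc_sizes, collapse = " -> "),
      " (ReLU) -> softmax(", x$output_dim, ")\n", sep = "")
  if (x$trained)
    cat(sprintf("  trained: %d epochs, final loss %.4f\n", x$epochs_run,
                utils::tail(x$loss_trace, 1)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.gait_lstm <- function(object, ...) object$params

#' @export
plot.gait_lstm <- function(x, ...) {
  if (!length(x$loss_trace)) stop("model has no loss trace (untrained)")
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "training loss",
       main = "LSTM training loss", ...)
  invisible(x)
}
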