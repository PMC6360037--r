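#' Hidden-layer growth rule for the MLP family
#'
#' Generates the hidden-size ladder used to sweep MLP depth: the first
#' additional layer has 32 units and each further layer doubles the
#' previous one, so `k` layers give `32, 64, ..., 32 * 2^(k-1)`. The
#' best-performing configuration places the widest layer first (input
#' side): `rev(mlp_layer_growth(4))` = 256, 128, 64, 32, which is the
#' package default.
#'
#' @param n_layers number of hidden layers (0 gives the logistic-regression
#'   baseline with no hidden layer).
#' @return Integer vector of hidden sizes in growth order.
#' @export
mlp_layer_growth <- function(n_layers) {
  stopifnot(n_layers >= 0L)
  if (n_layers == 0L) return(integer(0))
  as.integer(32 * 2^(seq_len(n_layers) - 1L))
}

#' Build an (untrained) multilayer perceptron
#'
#' A fully connected stack `input -> hidden layers (ReLU) -> softmax(4)`
#' with one dropout layer after the first hidden layer. With
#' `hidden_sizes = integer(0)` the model reduces to multinomial logistic
#' regression (a single softmax layer). Weights are Glorot-uniform
#' initialized; call [train_mlp()] (or the [gait_mlp()] front end) to fit.
#'
#' @param input_dim input dimensionality (1620 for spectral features).
#' @param hidden_sizes ordered hidden-layer widths; default
#'   `c(256, 128, 64, 32)`.
#' @param dropout_rate fraction of first-hidden-layer units dropped during
#'   training, in \[0, 1); default 0.5.
#' @param output_dim number of classes (4 forms).
#' @param seed seed for weight initialization.
#' @return An object of class `gait_mlp` (untrained).
#' @export
build_mlp <- function(input_dim = 1620L, hidden_sizes = c(256L, 128L, 64L, 32L),
                      dropout_rate = 0.5, output_dim = 4L, seed = 1L) {
  stopifnot(input_dim >= 1L, all(hidden_sizes >= 1L),
            dropout_rate >= 0, dropout_rate < 1)
  set.seed(as.integer(seed))
  dims <- c(input_dim, hidden_sizes, output_dim)
  params <- list()
  for (l in seq_len(length(dims) - 1L)) {
    params[[paste0("W", l)]] <- .glorot(dims[l], dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  structure(list(params = params, hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 trained = FALSE, loss_trace = numeric(0),
                 feature_center = NULL, feature_scale = NULL),
            class = "gait_mlp")
}

# forward pass; returns probs and (optionally) layer caches for backprop.
# `masks` supplies dropout masks (training) or NULL (inference).
.mlp_forward <- function(params, x, n_hidden, masks = NULL) {
  a <- x
  cache <- list(a0 = x)
  for (l in seq_len(n_hidden)) {
    z <- .addb(a %*% params[[paste0("W", l)]], params[[paste0("b", l)]])
    a <- .relu(z)
    if (!is.null(masks) && l == 1L && !is.null(masks$drop))
      a <- a * masks$drop
    cache[[paste0("z", l)]] <- z
    cache[[paste0("a", l)]] <- a
  }
  lo <- n_hidden + 1L
  logits <- .addb(a %*% params[[paste0("W", lo)]], params[[paste0("b", lo)]])
  probs <- .softmax(logits)
  list(probs = probs, cache = cache)
}

# gradient of the 1/(N*M)-normalized cross entropy w.r.t. all parameters
.mlp_backward <- function(params, fw, y_onehot, n_hidden, masks = NULL) {
  n <- nrow(y_onehot); m <- ncol(y_onehot)
  grads <- list()
  delta <- (fw$probs - y_onehot) / (n * m)      # dL/dlogits
  for (l in seq(n_hidden + 1L, 1L)) {
    a_prev <- fw$cache[[paste0("a", l - 1L)]] %||% fw$cache$a0
    grads[[paste0("W", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params[[paste0("W", l)]])
      if (!is.null(masks) && (l - 1L) == 1L && !is.null(masks$drop))
        delta <- delta * masks$drop
      delta <- delta * (fw$cache[[paste0("z", l - 1L)]] > 0)
    }
  }
  grads
}

#' Train a multilayer perceptron
#'
#' Adam (default parameters) on the `1/(N*M)`-normalized categorical
#' cross-entropy, minibatches of `cfg$batch_size` reshuffled every epoch,
#' inverted dropout after the first hidden layer. Training stops at the
#' end of the first epoch whose full-training-set loss falls below
#' `cfg$mlp_loss_threshold` (0.10), with a hard cap of
#' `cfg$mlp_max_epochs` (500) epochs. Features are standardized (center /
#' scale stored on the model and re-applied at prediction).
#'
#' @param model a [build_mlp()] object.
#' @param x `n x input_dim` feature matrix.
#' @param y integer form labels (1..4).
#' @param cfg a [train_config()].
#' @return The trained `gait_mlp`, with `$loss_trace` (one entry per
#'   epoch) and `$epochs_run`.
#' @export
train_mlp <- function(model, x, y, cfg = train_config()) {
  stopifnot(inherits(model, "gait_mlp"), nrow(x) == length(y))
  if (length(unique(y)) < 2L)
    stop("training set must contain at least 2 classes")
  set.seed(cfg$seed)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd); scl[scl < 1e-8] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  Y <- .one_hot(y, model$output_dim)
  params <- model$params
  nh <- length(model$hidden_sizes)
  opt <- .adam_init(params)
  n <- nrow(xs)
  keep_p <- 1 - model$dropout_rate
  trace <- numeric(0)
  for (epoch in seq_len(cfg$mlp_max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xs[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      masks <- NULL
      if (nh >= 1L && model$dropout_rate > 0) {
        masks <- list(drop = matrix(
          stats::rbinom(length(idx) * model$hidden_sizes[1], 1L, keep_p),
          length(idx)) / keep_p)
      }
      fw <- .mlp_forward(params, xb, nh, masks)
      if (!all(is.finite(fw$probs)))
        stop("non-finite network output at epoch ", epoch)
      gr <- .mlp_backward(params, fw, yb, nh, masks)
      st <- .adam_step(opt, params, gr)
      opt <- st$state; params <- st$params
    }
    full <- .mlp_forward(params, xs, nh)$probs
    loss <- suppressWarnings(categorical_cross_entropy(Y, full))
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
    trace <- c(trace, loss)
    if (loss < cfg$mlp_loss_threshold) break
  }
  model$params <- params
  model$trained <- TRUE
  model$loss_trace <- trace
  model$epochs_run <- length(trace)
  model$feature_center <- ctr
  model$feature_scale <- scl
  model$cfg <- cfg
  model
}

#' Fit an MLP form classifier (build + train front end)
#'
#' @inheritParams train_mlp
#' @inheritParams build_mlp
#' @return A trained `gait_mlp`.
#' @export
gait_mlp <- function(x, y, hidden_sizes = c(256L, 128L, 64L, 32L),
                     dropout_rate = 0.5, cfg = train_config()) {
  model <- build_mlp(ncol(x), hidden_sizes, dropout_rate, seed = cfg$seed)
  train_mlp(model, x, y, cfg)
}

#' @export
predict.gait_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else rbind(newdata)
  if (!is.null(object$feature_center))
    x <- sweep(sweep(x, 2L, object$feature_center), 2L,
               object$feature_scale, "/")
  probs <- .mlp_forward(object$params, x,
                        length(object$hidden_sizes))$probs
  colnames(probs) <- paste0("form", seq_len(object$output_dim))
  if (type == "class") max.col(probs, ties.method = "first") else probs
}

#' @export
print.gait_mlp <- function(x, ...) {
  cat("<gait_mlp> ", x$input_dim, " -> ",
      if (length(x$hidden_sizes))
        paste(x$hidden_sizes, collapse = " -> ") else "(no hidden)",
      " -> softmax(", x$output_dim, "), dropout ", x$dropout_rate, "\n",
      sep = "")
  if (x$trained)
    cat(sprintf("  trained: %d epochs, final loss %.4f\n",
                x$epochs_run, utils::tail(x$loss_trace, 1)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.gait_mlp <- function(object, ...) object$params

#' @export
plot.gait_mlp <- function(x, ...) {
  if (!length(x$loss_trace)) stop("model has no loss trace (untrained)")
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "training loss",
       main = "MLP training loss", ...)
  graphics::abline(h = 0.10, lty = 2)
  invisible(x)
}
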