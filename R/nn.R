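# Shared neural-network numerics: initialization, activations, Adam.
# Parameters are flat named lists of matrices/vectors; gradients mirror
# that structure. All math is dense base-R matrix algebra (BLAS-backed).

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.relu <- function(x) (x > 0) * x

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# broadcast a bias row-vector over a matrix
.addb <- function(x, b) sweep(x, 2L, b, "+")

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * grads[[k]]
    state$v[[k]] <- state$beta2 * state$v[[k]] +
      (1 - state$beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] - state$lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + state$eps)
  }
  list(state = state, params = params)
}

#' Training configuration for the neural classifiers
#'
#' Defaults follow the reference training regime: minibatches of 100 with
#' reshuffling at the start of every epoch, Adam with default parameters,
#' MLP training stopped when the training loss drops below 0.10 (hard cap
#' 500 epochs), LSTM training always run for exactly 15 epochs.
#'
#' @param batch_size minibatch size.
#' @param mlp_loss_threshold stop threshold on the full-training-set loss.
#' @param mlp_max_epochs hard cap on MLP epochs.
#' @param lstm_epochs fixed LSTM epoch count.
#' @param seed integer seed governing initialization, shuffling, dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 100L, mlp_loss_threshold = 0.10,
                         mlp_max_epochs = 500L, lstm_epochs = 15L,
                         seed = 1L) {
  stopifnot(batch_size >= 1L, mlp_loss_threshold > 0,
            mlp_max_epochs >= 1L, lstm_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 mlp_loss_threshold = mlp_loss_threshold,
                 mlp_max_epochs = as.integer(mlp_max_epochs),
                 lstm_epochs = as.integer(lstm_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}
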