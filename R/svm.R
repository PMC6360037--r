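#' Radial-basis SVM baseline on spectral features
#'
#' A thin front end over [e1071::svm()] (libsvm): a multiclass
#' maximum-margin classifier with a radial-basis kernel on the 1620-dim
#' spectral vectors, used as the non-neural baseline. libsvm handles
#' multiclass by one-vs-one voting. Features are standardized inside
#' libsvm, so the kernel width defaults to `1 / (n_features * var)` with
#' `var = 1` on the scaled data; cost defaults to 1. Hyperparameters are
#' recorded on the returned object.
#'
#' @param x `n x d` feature matrix.
#' @param y integer form labels (1..4).
#' @param cost soft-margin cost C.
#' @param gamma kernel width; `NULL` for the variance-scaled default.
#' @return An object of class `gait_svm` wrapping the fitted svm.
#' @export
gait_svm <- function(x, y, cost = 1, gamma = NULL) {
  if (length(unique(y)) < 2L)
    stop("training set must contain at least 2 classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  # only scale non-constant columns (the normalized fundamental is
  # identically 1 by construction and must not trip the scaler)
  scale_cols <- apply(x, 2L, stats::sd) > 1e-9
  fit <- e1071::svm(x, factor(y, levels = 1:4), kernel = "radial",
                    cost = cost, gamma = gamma, scale = scale_cols)
  structure(list(fit = fit, cost = cost, gamma = gamma),
            class = "gait_svm")
}

#' @export
predict.gait_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cls <- as.integer(as.character(predict(object$fit, newdata)))
  if (type == "class") return(cls)
  .one_hot(cls, 4L)   # hard assignments as degenerate distributions
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf("<gait_svm> RBF kernel, C = %g, gamma = %.3g, %d SVs\n",
              x$cost, x$gamma, x$fit$tot.nSV))
  invisible(x)
}
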