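#' Categorical cross-entropy loss
#'
#' The training criterion for both networks:
#' \deqn{L = -\frac{1}{N M} \sum_{n} \sum_{m} y_t[n,m] \, \ln y_p[n,m]}
#' where `y_t` is the one-hot ground truth, `y_p` the predicted class
#' distribution, `N` the number of samples and `M = 4` the number of
#' forms. Note the `1/(N*M)` normalization: the uniform predictor scores
#' `ln(M)/M` (about 0.3466 for four classes), and the 0.10 training-stop
#' threshold is stated on this scale.
#'
#' Predicted probabilities are clipped below at `1e-12` (with a warning
#' when the clip is active at a true class) so that a confidently wrong
#' prediction yields a large finite loss rather than `Inf`.
#'
#' @param y_true `N x M` one-hot matrix.
#' @param y_pred `N x M` matrix of class probabilities (rows sum to 1).
#' @return Scalar loss.
#' @export
categorical_cross_entropy <- function(y_true, y_pred) {
  stopifnot(is.matrix(y_true), is.matrix(y_pred),
            all(dim(y_true) == dim(y_pred)))
  if (any(abs(rowSums(y_true) - 1) > 1e-9) ||
      any(y_true != 0 & abs(y_true - 1) > 1e-9))
    stop("`y_true` rows must be one-hot (a single 1 per row)")
  clipped <- y_pred < 1e-12 & y_true > 0
  if (any(clipped))
    warning(sum(clipped), " zero predicted probability(ies) at a true ",
            "class clipped to 1e-12")
  -sum(y_true * log(pmax(y_pred, 1e-12))) / (nrow(y_true) * ncol(y_true))
}
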