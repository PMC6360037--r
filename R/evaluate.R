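#' Aggregate per-trial / per-window predictions to the patient level
#'
#' Each prediction is reduced to its argmax form and counted; a patient's
#' predicted form is the most frequent one over all their trials (MLP /
#' SVM granularity) or windows (LSTM granularity). Frequency ties break
#' toward the lower form index and are flagged, since neighbouring forms
#' can genuinely overlap clinically.
#'
#' @param pred_forms integer vector of predicted forms (argmax already
#'   taken), or an `n x 4` probability matrix (argmax taken rowwise).
#' @param patient_id character vector parallel to the predictions.
#' @param true_form integer vector parallel to the predictions (each
#'   patient must have a single consistent label).
#' @return A data.frame of class `patient_scores`: one row per patient
#'   with columns `patient_id`, `true_form`, `pred_form`, `tie`,
#'   `n_predictions` and frequency columns `f1..f4`.
#' @export
aggregate_patients <- function(pred_forms, patient_id, true_form) {
  if (is.matrix(pred_forms))
    pred_forms <- max.col(pred_forms, ties.method = "first")
  stopifnot(length(pred_forms) == length(patient_id),
            length(pred_forms) == length(true_form))
  ids <- unique(patient_id)
  rows <- lapply(ids, function(pid) {
    sel <- patient_id == pid
    tf <- unique(true_form[sel])
    if (length(tf) != 1L)
      stop("patient ", pid, " carries inconsistent true forms")
    freq <- tabulate(pred_forms[sel], nbins = 4L)
    top <- which(freq == max(freq))
    data.frame(patient_id = pid, true_form = tf, pred_form = top[1],
               tie = length(top) > 1L, n_predictions = sum(sel),
               f1 = freq[1], f2 = freq[2], f3 = freq[3], f4 = freq[4])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("patient_scores", "data.frame")
  out
}

.freq_matrix <- function(scores) {
  as.matrix(scores[, c("f1", "f2", "f3", "f4")])
}

#' Patient-level top-k accuracy
#'
#' A patient counts as correct at `k` if their true form is among the `k`
#' most frequently predicted forms (frequency ranks, ties toward the lower
#' index). Per-form accuracies are computed over each form's test
#' patients; the overall accuracy is patient-weighted.
#'
#' @param scores a [aggregate_patients()] result.
#' @param k 1 or 2.
#' @return List with `per_form` (length-4 named vector, `NA` for forms
#'   with no patients) and `overall`.
#' @export
topk_accuracy <- function(scores, k = 1L) {
  stopifnot(inherits(scores, "patient_scores"), k %in% 1:2)
  if (!nrow(scores)) stop("empty score list")
  freq <- .freq_matrix(scores)
  correct <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(-freq[i, ], 1:4)        # rank by frequency, low index first
    scores$true_form[i] %in% ord[seq_len(k)]
  }, logical(1))
  per_form <- vapply(1:4, function(f) {
    sel <- scores$true_form == f
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  names(per_form) <- paste0("form", 1:4)
  list(per_form = per_form, overall = mean(correct))
}

#' Patient-level confusion matrix
#'
#' Entry (i, j) counts test patients of true form i whose top-1 predicted
#' form is j; row sums equal each form's test patient count.
#'
#' @param scores a [aggregate_patients()] result.
#' @return 4 x 4 integer matrix (rows = ground truth, cols = predicted).
#' @export
confusion <- function(scores) {
  stopifnot(inherits(scores, "patient_scores"))
  if (!nrow(scores)) stop("empty score list")
  m <- matrix(0L, 4L, 4L,
              dimnames = list(true = paste0("form", 1:4),
                              pred = paste0("form", 1:4)))
  for (i in seq_len(nrow(scores)))
    m[scores$true_form[i], scores$pred_form[i]] <-
      m[scores$true_form[i], scores$pred_form[i]] + 1L
  m
}

#' Build a full evaluation report
#'
#' @param scores a [aggregate_patients()] result.
#' @param model_name label stored on the report.
#' @return An `eval_report`: per-form and overall top-1/top-2 accuracies
#'   plus the confusion matrix.
#' @export
eval_report <- function(scores, model_name = "model") {
  t1 <- topk_accuracy(scores, 1L)
  t2 <- topk_accuracy(scores, 2L)
  structure(list(model = model_name,
                 top1 = t1$per_form, top2 = t2$per_form,
                 overall_top1 = t1$overall, overall_top2 = t2$overall,
                 confusion = confusion(scores),
                 n_patients = nrow(scores),
                 n_ties = sum(scores$tie)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$model, "-", x$n_patients, "patients",
      if (x$n_ties) paste0("(", x$n_ties, " tie(s))") else "", "\n")
  tab <- rbind(T1 = c(x$top1, overall = x$overall_top1),
               T2 = c(x$top2, overall = x$overall_top2))
  print(round(tab, 3))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to CSV files
#'
#' Emits `<prefix>_accuracy.csv` (per-form rows, T1/T2 columns) and
#' `<prefix>_confusion.csv`.
#'
#' @param report an [eval_report()].
#' @param prefix output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  acc <- data.frame(form = c(paste0("form", 1:4), "overall"),
                    T1 = c(report$top1, report$overall_top1),
                    T2 = c(report$top2, report$overall_top2))
  p1 <- paste0(prefix, "_accuracy.csv")
  p2 <- paste0(prefix, "_confusion.csv")
  utils::write.csv(acc, p1, row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion), p2, row.names = TRUE)
  invisible(c(p1, p2))
}
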