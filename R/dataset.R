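#' Patient-wise train/test split
#'
#' Patients (never trials) are randomly partitioned within each form at the
#' given ratio, so that no patient contributes data to both sides. The
#' train count is rounded to nearest with at least one train and one test
#' patient per form. Deterministic under `seed`.
#'
#' @param trials list of [gait_trial()] (only `patient_id`/`form` are used),
#'   or a `gait_dataset`.
#' @param ratio training fraction, default 0.75.
#' @param seed integer seed.
#' @return An object of class `dataset_split`: list with character vectors
#'   `train_patients`, `test_patients`, plus `ratio` and `seed`.
#' @export
split_patients <- function(trials, ratio = 0.75, seed = 1L) {
  if (inherits(trials, "gait_dataset")) trials <- trials$trials
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)")
  pid <- vapply(trials, `[[`, "", "patient_id")
  form <- as.integer(vapply(trials, function(t) as.numeric(t$form),
                            numeric(1)))
  pat <- unique(data.frame(patient_id = pid, form = form))
  set.seed(as.integer(seed))
  train <- character(0); test <- character(0)
  for (f in sort(unique(pat$form))) {
    ids <- sort(pat$patient_id[pat$form == f])
    n <- length(ids)
    if (n < 2L)
      stop("cannot split: form ", f, " has fewer than 2 patients")
    n_train <- min(max(round(ratio * n), 1L), n - 1L)
    tr <- sample(ids, n_train)
    train <- c(train, tr)
    test <- c(test, setdiff(ids, tr))
  }
  structure(list(train_patients = train, test_patients = test,
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>", length(x$train_patients), "train /",
      length(x$test_patients), "test patients (ratio", x$ratio, ")\n")
  invisible(x)
}

#' Duplicate training items of a minority form
#'
#' Every training item of `form` is repeated `factor - 1` extra times;
#' other forms are untouched. Used to double form-1 trials, whose clinical
#' prevalence is lowest. Augmentation applies to training data only; never
#' augment a test set. Content is never altered, only multiplicity.
#'
#' @param items list of objects carrying a `$form` field (trials, spectral
#'   features, window sets, ...).
#' @param form the form to augment.
#' @param factor total multiplicity (2 = doubled); `1` returns the input
#'   unchanged.
#' @return The augmented list (duplicates appended at the end).
#' @export
augment_form <- function(items, form, factor = 2L) {
  if (factor < 1L) stop("`factor` must be >= 1")
  if (factor == 1L) return(items)
  is_f <- vapply(items, function(x) isTRUE(x$form == form), logical(1))
  c(items, rep(items[is_f], factor - 1L))
}

.one_hot <- function(y, m = 4L) {
  Y <- matrix(0, length(y), m)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

.assert_disjoint <- function(train_pids, test_pids) {
  both <- intersect(unique(train_pids), unique(test_pids))
  if (length(both))
    stop("patient id(s) cross the train/test boundary: ",
         paste(both, collapse = ", "))
}

#' Assemble the spectral (MLP/SVM) dataset
#'
#' One example per trial: the 81 x 20 spectral matrix flattened row-major
#' to a length-1620 vector, with a one-hot form label. Patients follow the
#' split; patient-disjointness between train and test is asserted.
#'
#' @param spectra list of [spectral_features()] (train-side augmentation,
#'   if any, applied beforehand with [augment_form()]).
#' @param split a [split_patients()] result.
#' @return List with `train` and `test`, each a `labeled_examples` list:
#'   `x` (n x 1620 matrix), `y` (integer forms), `Y` (n x 4 one-hot),
#'   `patient_id`, `trial_id`, `mode = "spectral"`.
#' @export
assemble_mlp_dataset <- function(spectra, split) {
  stopifnot(inherits(split, "dataset_split"))
  keep <- vapply(spectra, function(s)
    inherits(s, "spectral_features") && !is.na(s$form), logical(1))
  if (any(!keep))
    warning(sum(!keep), " trial(s) lacking spectral features were skipped")
  spectra <- spectra[keep]
  pid <- vapply(spectra, `[[`, "", "patient_id")
  part <- ifelse(pid %in% split$train_patients, "train",
                 ifelse(pid %in% split$test_patients, "test", NA))
  if (anyNA(part)) stop("patient(s) not assigned by the split: ",
                        paste(unique(pid[is.na(part)]), collapse = ", "))
  build <- function(sel) {
    ss <- spectra[sel]
    x <- t(vapply(ss, spectral_vector, numeric(1620L)))
    y <- vapply(ss, function(s) as.integer(s$form), 0L)
    structure(list(x = x, y = y, Y = .one_hot(y),
                   patient_id = vapply(ss, `[[`, "", "patient_id"),
                   trial_id = vapply(ss, `[[`, "", "trial_id"),
                   mode = "spectral"),
              class = "labeled_examples")
  }
  out <- list(train = build(part == "train"), test = build(part == "test"))
  .assert_disjoint(out$train$patient_id, out$test$patient_id)
  out
}

#' Assemble the sequence (LSTM) dataset
#'
#' One example per window: a 75 x 81 angle sequence with a one-hot form
#' label; every window inherits its parent trial's patient and label.
#'
#' @param window_sets list of [window_sequences()] results.
#' @param split a [split_patients()] result.
#' @return List with `train`/`test` `labeled_examples`: `x` is an
#'   `n x 75 x 81` array, `mode = "window"`.
#' @export
assemble_rnn_dataset <- function(window_sets, split) {
  stopifnot(inherits(split, "dataset_split"))
  keep <- vapply(window_sets, function(w)
    inherits(w, "window_set") && !is.na(w$form), logical(1))
  if (any(!keep))
    warning(sum(!keep), " trial(s) lacking windows were skipped")
  window_sets <- window_sets[keep]
  pid <- vapply(window_sets, `[[`, "", "patient_id")
  part <- ifelse(pid %in% split$train_patients, "train",
                 ifelse(pid %in% split$test_patients, "test", NA))
  if (anyNA(part)) stop("patient(s) not assigned by the split: ",
                        paste(unique(pid[is.na(part)]), collapse = ", "))
  build <- function(sel) {
    ws <- window_sets[sel]
    nw <- vapply(ws, function(w) length(w$windows), 0L)
    n <- sum(nw)
    dims <- dim(ws[[1]]$windows[[1]])
    x <- array(NA_real_, c(n, dims[1], dims[2]))
    y <- integer(n); pids <- character(n); tids <- character(n)
    i <- 0L
    for (w in ws) for (win in w$windows) {
      i <- i + 1L
      x[i, , ] <- win
      y[i] <- w$form; pids[i] <- w$patient_id; tids[i] <- w$trial_id
    }
    structure(list(x = x, y = y, Y = .one_hot(y), patient_id = pids,
                   trial_id = tids, mode = "window"),
              class = "labeled_examples")
  }
  out <- list(train = build(part == "train"), test = build(part == "test"))
  .assert_disjoint(out$train$patient_id, out$test$patient_id)
  out
}

#' @export
print.labeled_examples <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf("<labeled_examples> %d %s examples; per form: %s\n", n,
              x$mode, paste(tabulate(x$y, 4), collapse = "/")))
  invisible(x)
}

#' Write a split manifest CSV (`patient_id,form,partition`)
#' @param split a `dataset_split`.
#' @param trials the trials the split was made from (for form lookup).
#' @param path output path.
#' @export
write_split_manifest <- function(split, trials, path) {
  if (inherits(trials, "gait_dataset")) trials <- trials$trials
  pid <- vapply(trials, `[[`, "", "patient_id")
  form <- vapply(trials, `[[`, 0L, "form")
  pat <- unique(data.frame(patient_id = pid, form = form))
  pat$partition <- ifelse(pat$patient_id %in% split$train_patients,
                          "train", "test")
  utils::write.csv(pat[order(pat$form, pat$patient_id), ], path,
                   row.names = FALSE)
  invisible(path)
}
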