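# lightweight stand-ins carrying just the fields the dataset module uses
dummy_trial <- function(pid, form, tid = paste0(pid, "-t1"))
  list(patient_id = pid, form = form, trial_id = tid)

dummy_spectra <- function(pid, form, tid) {
  structure(list(coeffs = matrix(runif(81 * 20), 81, 20,
                                 dimnames = list(angle_feature_names(),
                                                 paste0("h", 0:19))),
                 n_steps = 3L, trial_id = tid, patient_id = pid,
                 form = form),
            class = "spectral_features")
}

dummy_windows <- function(pid, form, tid, n_win = 3L) {
  structure(list(windows = replicate(n_win, matrix(runif(75 * 81), 75, 81),
                                     simplify = FALSE),
                 starts = (seq_len(n_win) - 1L) * 15L,
                 trial_id = tid, patient_id = pid, form = form),
            class = "window_set")
}

test_that("patient split honours the ratio with at least one test patient", {
  trials <- unlist(lapply(1:4, function(f)
    lapply(1:12, function(i)
      dummy_trial(sprintf("F%dP%02d", f, i), f))), recursive = FALSE)
  sp <- split_patients(trials, ratio = 0.75, seed = 42L)
  for (f in 1:4) {
    ids <- sprintf("F%dP%02d", f, 1:12)
    expect_identical(sum(ids %in% sp$train_patients), 9L)
    expect_identical(sum(ids %in% sp$test_patients), 3L)
  }
  expect_length(intersect(sp$train_patients, sp$test_patients), 0L)

  sp2 <- split_patients(trials, ratio = 0.75, seed = 42L)
  expect_identical(sp, sp2)                     # deterministic under seed

  expect_error(split_patients(list(dummy_trial("a", 1), dummy_trial("b", 2),
                                   dummy_trial("c", 2)),
                              seed = 1L),
               "fewer than 2 patients")
})

test_that("patient-disjointness holds across 100 random synthetic cohorts", {
  set.seed(77)
  for (rep in 1:100) {
    n_per_form <- sample(2:9, 4, replace = TRUE)
    trials <- list()
    for (f in 1:4) for (i in seq_len(n_per_form[f]))
      for (k in seq_len(sample(1:3, 1)))
        trials[[length(trials) + 1L]] <-
          dummy_trial(sprintf("r%dF%dP%d", rep, f, i), f,
                      sprintf("r%dF%dP%d-t%d", rep, f, i, k))
    sp <- split_patients(trials, seed = rep)
    expect_length(intersect(sp$train_patients, sp$test_patients), 0L)
    pids <- unique(vapply(trials, `[[`, "", "patient_id"))
    expect_setequal(c(sp$train_patients, sp$test_patients), pids)
  }
})

test_that("augmentation doubles the target form and only that form", {
  set.seed(1)
  items <- c(lapply(1:47, function(i)
               dummy_trial(sprintf("F1P%02d", i), 1L)),
             lapply(1:60, function(i)
               dummy_trial(sprintf("F2P%02d", i), 2L)))
  out <- augment_form(items, 1L, factor = 2L)
  forms <- vapply(out, `[[`, 0L, "form")
  expect_identical(sum(forms == 1L), 94L)
  expect_identical(sum(forms == 2L), 60L)
  # only multiplicity changes: the set of distinct trial ids is unchanged
  expect_setequal(vapply(out, `[[`, "", "trial_id"),
                  vapply(items, `[[`, "", "trial_id"))
  expect_identical(augment_form(items, 1L, factor = 1L), items)
  # sequence-level bookkeeping: doubling 1404 windows gives 2808
  seqs <- rep(list(dummy_trial("F1P01", 1L)), 1404L)
  expect_length(augment_form(seqs, 1L, 2L), 2808L)
})

test_that("assembled spectral datasets have one 1620-vector per trial", {
  set.seed(2)
  spectra <- list(); trials <- list()
  for (f in 1:4) for (i in 1:4) {
    pid <- sprintf("F%dP%d", f, i)
    trials[[length(trials) + 1L]] <- dummy_trial(pid, f)
    spectra[[length(spectra) + 1L]] <-
      dummy_spectra(pid, f, paste0(pid, "-t1"))
  }
  sp <- split_patients(trials, seed = 5L)
  ds <- assemble_mlp_dataset(spectra, sp)
  expect_identical(ncol(ds$train$x), 1620L)
  expect_identical(nrow(ds$train$x) + nrow(ds$test$x), 16L)
  expect_equal(rowSums(ds$train$Y), rep(1, length(ds$train$y)))
  # label conservation: one-hot column sums equal per-form example counts
  expect_equal(colSums(ds$train$Y), tabulate(ds$train$y, 4L))
  expect_length(intersect(ds$train$patient_id, ds$test$patient_id), 0L)
})

test_that("assembled window datasets have one example per window", {
  set.seed(3)
  wsets <- list(); trials <- list()
  for (f in 1:2) for (i in 1:3) {
    pid <- sprintf("F%dP%d", f, i)
    trials[[length(trials) + 1L]] <- dummy_trial(pid, f)
    wsets[[length(wsets) + 1L]] <-
      dummy_windows(pid, f, paste0(pid, "-t1"), n_win = 45L)
  }
  # 2 more forms so the split is valid
  for (f in 3:4) for (i in 1:2) {
    pid <- sprintf("F%dP%d", f, i)
    trials[[length(trials) + 1L]] <- dummy_trial(pid, f)
    wsets[[length(wsets) + 1L]] <-
      dummy_windows(pid, f, paste0(pid, "-t1"), n_win = 45L)
  }
  sp <- split_patients(trials, seed = 6L)
  ds <- assemble_rnn_dataset(wsets, sp)
  n_all <- dim(ds$train$x)[1] + dim(ds$test$x)[1]
  expect_identical(n_all, 10L * 45L)
  expect_identical(dim(ds$train$x)[2:3], c(75L, 81L))
  expect_length(intersect(ds$train$patient_id, ds$test$patient_id), 0L)
  # windows keep their parent label
  expect_true(all(ds$train$y %in% 1:4))
  expect_equal(colSums(ds$train$Y), tabulate(ds$train$y, 4L))
})
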