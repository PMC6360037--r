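#' Resolved run configuration
#'
#' Collects every tunable of the pipeline with the reference defaults:
#' subsampling 100 -> 50 frames/sec (factor 2), windows of 75 frames
#' displaced by 15 and capped at 45 per trial, 20 spectral harmonics,
#' patient-wise 0.75 split, form-1 training data doubled, minibatch 100,
#' MLP stop at loss < 0.10 (cap 500 epochs), LSTM 15 epochs. Every run
#' writes its resolved configuration next to its outputs so results are
#' regenerable from the run directory alone.
#'
#' @param n_per_form patients per form for the synthetic study.
#' @param trials_per_patient trials per patient.
#' @param duration trial duration (s).
#' @param noise_sd marker noise (mm).
#' @param subsample_factor temporal decimation factor.
#' @param window_length,window_stride,max_windows window geometry.
#' @param harmonics retained spectral coefficients per angle.
#' @param split_ratio training fraction.
#' @param augment named list form -> multiplicity for training data.
#' @param mlp_hidden,lstm_units,lstm_fc network architecture.
#' @param dropout_rate MLP dropout.
#' @param batch_size,mlp_loss_threshold,mlp_max_epochs,lstm_epochs training
#'   regime (see [train_config()]).
#' @param seed root seed; all randomness derives from it.
#' @return A `gait_config` list.
#' @export
gait_config <- function(n_per_form = c(5, 17, 12, 26),
                        trials_per_patient = 3L, duration = 8,
                        noise_sd = 1, subsample_factor = 2L,
                        window_length = 75L, window_stride = 15L,
                        max_windows = 45L, harmonics = 20L,
                        split_ratio = 0.75, augment = list(`1` = 2L),
                        mlp_hidden = c(256L, 128L, 64L, 32L),
                        dropout_rate = 0.5, lstm_units = 128L,
                        lstm_fc = c(128L, 64L, 32L), batch_size = 100L,
                        mlp_loss_threshold = 0.10, mlp_max_epochs = 500L,
                        lstm_epochs = 15L, seed = 1L) {
  if (window_length < 1L || window_stride < 1L || max_windows < 1L)
    stop("window geometry must be positive")
  if (harmonics != 20L)
    stop("the spectral stage retains exactly 20 harmonics")
  structure(as.list(environment()), class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  for (k in names(x)) cat("  ", k, ": ",
                          paste(x[[k]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Preprocess and featurize one trial
#'
#' Subsample, detect gait events (unless supplied), trim to whole steps,
#' extract the 81-angle series, and derive spectral features and sequence
#' windows.
#'
#' @param trial a [gait_trial()].
#' @param config a [gait_config()].
#' @param events optional hand-annotated [gait_events()] for the
#'   *subsampled* trial.
#' @return List with `series`, `spectra`, `windows`, `steps`; `spectra`
#'   and/or `windows` are `NULL` (with a warning) when the trimmed trial
#'   is too short for them.
#' @export
featurize_trial <- function(trial, config = gait_config(), events = NULL) {
  sub <- subsample(trial, config$subsample_factor)
  if (is.null(events)) events <- detect_gait_events(sub)
  tr <- trim_to_complete_steps(sub, events)
  series <- angle_series(tr$trial, tr$steps)
  spectra <- tryCatch(spectral_features(series), error = function(e) {
    warning("trial ", trial$trial_id, ": ", conditionMessage(e)); NULL
  })
  windows <- tryCatch(
    window_sequences(series, config$window_length, config$window_stride,
                     config$max_windows),
    error = function(e) {
      warning("trial ", trial$trial_id, ": ", conditionMessage(e)); NULL
    })
  list(series = series, spectra = spectra, windows = windows,
       steps = tr$steps)
}

# duplicate train-side items of augmented forms (content untouched)
.augment_train <- function(items, split, augment) {
  for (f in names(augment)) {
    fac <- augment[[f]]
    if (fac <= 1L) next
    sel <- vapply(items, function(it)
      isTRUE(it$form == as.integer(f)) &&
        it$patient_id %in% split$train_patients, logical(1))
    items <- c(items, rep(items[sel], fac - 1L))
  }
  items
}

#' Run the full pipeline on a synthetic (or supplied) dataset
#'
#' simulate -> preprocess -> features -> patient-wise split -> augment ->
#' train MLP, LSTM and SVM -> patient-level evaluation. Writes accuracy
#' and confusion CSVs per classifier plus the resolved configuration, and
#' returns the three [eval_report()]s. Idempotent under a fixed seed.
#'
#' @param config a [gait_config()].
#' @param out_dir output directory (`NULL` to skip writing).
#' @param dataset optional pre-built `gait_dataset` (bypasses simulation).
#' @param verbose print stage progress.
#' @return Invisible list: `reports` (mlp/lstm/svm), `split`, `models`,
#'   `sequence_accuracy` (window-level LSTM test accuracy),
#'   `trial_accuracy` (trial-level MLP test accuracy), `config`.
#' @export
run_pipeline <- function(config = gait_config(), out_dir = NULL,
                         dataset = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  if (is.null(dataset)) {
    say("simulating ", sum(config$n_per_form), " patients x ",
        config$trials_per_patient, " trials")
    dataset <- generate_dataset(config$n_per_form,
                                config$trials_per_patient,
                                seed = seeds[1], duration = config$duration,
                                noise_sd = config$noise_sd)
  }
  say("preprocessing + features (", length(dataset$trials), " trials)")
  spectra <- list(); window_sets <- list()
  for (tr in dataset$trials) {
    ft <- tryCatch(featurize_trial(tr, config), error = function(e) {
      warning("stage features, trial ", tr$trial_id, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(ft)) next
    if (!is.null(ft$spectra)) spectra[[length(spectra) + 1L]] <- ft$spectra
    if (!is.null(ft$windows))
      window_sets[[length(window_sets) + 1L]] <- ft$windows
  }

  split <- split_patients(dataset, config$split_ratio, seed = seeds[2])
  spectra_aug <- .augment_train(spectra, split, config$augment)
  windows_aug <- .augment_train(window_sets, split, config$augment)
  mlp_data <- assemble_mlp_dataset(spectra_aug, split)
  rnn_data <- assemble_rnn_dataset(windows_aug, split)
  say("datasets: ", length(mlp_data$train$y), " train trials, ",
      dim(rnn_data$train$x)[1], " train windows")

  cfg_mlp <- train_config(config$batch_size, config$mlp_loss_threshold,
                          config$mlp_max_epochs, config$lstm_epochs,
                          seed = seeds[3])
  say("training MLP")
  mlp <- gait_mlp(mlp_data$train$x, mlp_data$train$y, config$mlp_hidden,
                  config$dropout_rate, cfg_mlp)
  say("training LSTM (", config$lstm_epochs, " epochs)")
  cfg_lstm <- train_config(config$batch_size, config$mlp_loss_threshold,
                           config$mlp_max_epochs, config$lstm_epochs,
                           seed = seeds[4])
  lstm <- gait_lstm(rnn_data$train$x, rnn_data$train$y, config$lstm_units,
                    config$lstm_fc, cfg_lstm)
  say("training SVM baseline")
  svm <- gait_svm(mlp_data$train$x, mlp_data$train$y)

  mlp_pred <- predict(mlp, mlp_data$test$x, type = "class")
  lstm_pred <- predict(lstm, rnn_data$test$x, type = "class")
  svm_pred <- predict(svm, mlp_data$test$x, type = "class")

  reports <- list(
    mlp = eval_report(aggregate_patients(mlp_pred, mlp_data$test$patient_id,
                                         mlp_data$test$y), "MLP"),
    lstm = eval_report(aggregate_patients(lstm_pred,
                                          rnn_data$test$patient_id,
                                          rnn_data$test$y), "LSTM"),
    svm = eval_report(aggregate_patients(svm_pred, mlp_data$test$patient_id,
                                         mlp_data$test$y), "SVM"))

  out <- list(reports = reports, split = split,
              models = list(mlp = mlp, lstm = lstm, svm = svm),
              data = list(mlp = mlp_data, rnn = rnn_data),
              sequence_accuracy = mean(lstm_pred == rnn_data$test$y),
              trial_accuracy = mean(mlp_pred == mlp_data$test$y),
              config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports))
      write_eval_report(reports[[nm]], file.path(out_dir, nm))
    write_split_manifest(split, dataset, file.path(out_dir, "split.csv"))
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    say("reports written to ", out_dir)
  }
  invisible(out)
}
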