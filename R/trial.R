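#' Construct a walking trial
#'
#' A trial is one recorded walk of one patient: an ordered sequence of
#' frames, each holding the 3D positions (millimetres, lab coordinates) of
#' the 19 markers of [gait_markers()]. The lab convention throughout the
#' package is X = direction of progression (anterior), Y = mediolateral
#' (subject's left positive), Z = vertical up.
#'
#' @param positions numeric array of dimension `n_frames x 19 x 3`; the
#'   second dimension must be named with the 19 marker identifiers (any
#'   order; stored in canonical order), the third with `c("x","y","z")`
#'   (optional).
#' @param frame_rate sampling rate in frames per second (> 0).
#' @param patient_id opaque patient identifier (single string), or `NA`.
#' @param form integer class label in 1..4, or `NA` if unlabelled.
#' @param trial_id optional trial identifier; defaults to a generated one.
#' @return An object of class `gait_trial`: a list with elements
#'   `positions` (array, markers in canonical order), `frame_rate`,
#'   `patient_id`, `form`, `trial_id`.
#' @export
gait_trial <- function(positions, frame_rate, patient_id = NA_character_,
                       form = NA_integer_, trial_id = NULL) {
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stop("`positions` must be a 3-dimensional array (frames x markers x xyz)")
  d <- dim(positions)
  if (d[2] != 19L || d[3] != 3L)
    stop("`positions` must be n_frames x 19 x 3, got ",
         paste(d, collapse = " x "))
  if (d[1] < 2L)
    stop("a trial must contain at least 2 frames, got ", d[1])
  mk <- dimnames(positions)[[2]]
  if (is.null(mk))
    stop("marker dimension of `positions` must be named")
  missing_mk <- setdiff(.GAIT_MARKERS, mk)
  if (length(missing_mk))
    stop("marker-set incomplete: missing ", paste(missing_mk, collapse = ", "))
  positions <- positions[, .GAIT_MARKERS, , drop = FALSE]
  dimnames(positions)[[3]] <- c("x", "y", "z")
  if (!all(is.finite(positions)))
    stop("marker coordinates must all be finite")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number")
  if (!is.na(form)) {
    form <- as.integer(form)
    if (!form %in% 1:4) stop("`form` must be in 1..4, got ", form)
  }
  if (is.null(trial_id))
    trial_id <- paste0("trial-", substr(basename(tempfile("")), 5, 12))
  structure(
    list(positions = positions, frame_rate = frame_rate,
         patient_id = as.character(patient_id), form = form,
         trial_id = as.character(trial_id)),
    class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  d <- dim(x$positions)
  cat("<gait_trial> ", x$trial_id, "\n", sep = "")
  cat(sprintf("  patient %s, form %s\n",
              x$patient_id, ifelse(is.na(x$form), "?", x$form)))
  cat(sprintf("  %d frames x 19 markers @ %g frames/sec (%.2f s)\n",
              d[1], x$frame_rate, d[1] / x$frame_rate))
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a `gait_trial`.
#' @return integer frame count.
#' @export
n_frames <- function(trial) dim(trial$positions)[1]

#' Extract one marker's trajectory
#' @param trial a `gait_trial`.
#' @param marker one of the 19 marker identifiers.
#' @return `n_frames x 3` numeric matrix with columns x, y, z.
#' @export
marker_xyz <- function(trial, marker) {
  if (!marker %in% .GAIT_MARKERS) stop("unknown marker id: ", marker)
  trial$positions[, marker, , drop = TRUE]
}
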