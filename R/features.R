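#' Orthographic projection onto a body plane
#'
#' Body planes are realized as lab-fixed orthographic projections under the
#' package's axis convention (X anterior, Y left, Z up): sagittal keeps
#' (X, Z), frontal keeps (Y, Z), transverse keeps (X, Y).
#'
#' @param point numeric length-3 vector or an `n x 3` matrix (mm).
#' @param plane one of `"sagittal"`, `"frontal"`, `"transverse"`.
#' @return A length-2 vector or `n x 2` matrix.
#' @export
project_to_plane <- function(point, plane) {
  idx <- switch(plane,
                sagittal = c(1L, 3L),
                frontal = c(2L, 3L),
                transverse = c(1L, 2L),
                stop("unknown plane: ", plane,
                     " (expected sagittal/frontal/transverse)"))
  if (is.matrix(point)) point[, idx, drop = FALSE] else point[idx]
}

#' Planar angle at a vertex marker
#'
#' The interior angle at `vertex` between the rays `vertex -> p1` and
#' `vertex -> p3`, in degrees within \[0, 180\]. Inputs may be single 2D
#' points or `n x 2` matrices (rowwise angles).
#'
#' @param p1,vertex,p3 2D points (length-2 vectors or `n x 2` matrices).
#' @return Angle(s) in degrees.
#' @export
triplet_angle <- function(p1, vertex, p3) {
  if (!is.matrix(p1)) { p1 <- rbind(p1); vertex <- rbind(vertex); p3 <- rbind(p3) }
  u <- p1 - vertex
  v <- p3 - vertex
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  bad <- which(nu < 1e-9 | nv < 1e-9)
  if (length(bad))
    stop("degenerate geometry: ray endpoint coincides with the vertex ",
         "(row ", bad[1], ")")
  # atan2 of cross and dot products: accurate near 0 and 180 degrees,
  # where the acos-of-cosine form loses ~sqrt(eps) of precision
  cross <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  ang <- atan2(abs(cross), rowSums(u * v)) * 180 / pi
  if (length(ang) == 1L) ang[[1]] else ang
}

#' Extract the 81 triplet angles per frame
#'
#' For every frame, all markers are projected onto the three body planes
#' and the 27 triplet angles of [gait_triplets()] are measured in each
#' plane, yielding 81 angles per frame. Ordering is plane-major (sagittal,
#' frontal, transverse), triplets in canonical row order within each plane;
#' see [angle_feature_names()].
#'
#' @param trial a trimmed, subsampled [gait_trial()].
#' @param steps optional `step_summary` from [trim_to_complete_steps()];
#'   its step count is carried on the result for spectral analysis.
#' @return An object of class `angle_series`: list with `values`
#'   (`n_frames x 81` matrix, degrees), `frame_rate`, `n_steps`,
#'   `trial_id`, `patient_id`, `form`.
#' @export
angle_series <- function(trial, steps = NULL) {
  stopifnot(inherits(trial, "gait_trial"))
  nf <- n_frames(trial)
  tr <- .GAIT_TRIPLETS
  out <- matrix(NA_real_, nf, 81L)
  colnames(out) <- angle_feature_names()
  k <- 0L
  for (pl in .GAIT_PLANES) {
    proj <- lapply(.GAIT_MARKERS, function(m)
      project_to_plane(marker_xyz(trial, m), pl))
    names(proj) <- .GAIT_MARKERS
    for (t in seq_len(nrow(tr))) {
      k <- k + 1L
      out[, k] <- tryCatch(
        triplet_angle(proj[[tr[t, "p1"]]], proj[[tr[t, "vertex"]]],
                      proj[[tr[t, "p3"]]]),
        error = function(e)
          stop("degenerate geometry in plane '", pl, "', triplet ", t,
               " (vertex ", tr[t, "vertex"], "): ", conditionMessage(e)))
    }
  }
  structure(list(values = out, frame_rate = trial$frame_rate,
                 n_steps = if (is.null(steps)) NA_integer_ else steps$n_steps,
                 trial_id = trial$trial_id, patient_id = trial$patient_id,
                 form = trial$form),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s: %d frames x 81 angles, N = %s steps\n",
              x$trial_id, nrow(x$values),
              ifelse(is.na(x$n_steps), "?", x$n_steps)))
  invisible(x)
}

#' Step-synchronized spectral features
#'
#' The discrete Fourier transform of each angle's time series is taken over
#' the whole trimmed trial, which spans exactly `N` whole steps. Only the
#' coefficients at indices 0, N, 2N, ..., 19N are retained: these are the
#' harmonics of the single-step fundamental, so the feature grid is
#' comparable across trials regardless of how many steps each contains.
#' Amplitudes (complex magnitudes) are kept; the first retained coefficient
#' (index 0) is left unnormalized while the other 19 are divided by the
#' amplitude of the fundamental (index N) of the same angle.
#'
#' @param series an [angle_series()] with a known step count `N >= 1` and
#'   at least `20 * N` frames.
#' @return An object of class `spectral_features`: list with `coeffs`
#'   (81 x 20 non-negative matrix, rows ordered as
#'   [angle_feature_names()]), plus trial metadata.
#' @export
spectral_features <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  N <- series$n_steps
  if (is.na(N) || N < 1L)
    stop("series must carry a positive step count (trim the trial first)")
  f <- nrow(series$values)
  if (f < 20L * N)
    stop("insufficient length: spectral features need >= 20*N = ", 20L * N,
         " frames, got ", f)
  idx <- (0:19) * N + 1L
  co <- matrix(NA_real_, 81L, 20L)
  rownames(co) <- colnames(series$values)
  colnames(co) <- paste0("h", 0:19)
  zero_rows <- 0L
  for (a in seq_len(81L)) {
    amp <- Mod(stats::fft(series$values[, a])[idx])
    fund <- amp[2L]
    if (fund < 1e-12) {
      co[a, ] <- c(amp[1L], rep(0, 19L))
      zero_rows <- zero_rows + 1L
    } else {
      co[a, ] <- c(amp[1L], amp[-1L] / fund)
    }
  }
  if (zero_rows > 0L)
    warning(zero_rows, " angle(s) had a vanishing fundamental; ",
            "their normalized harmonics were set to 0")
  structure(list(coeffs = co, n_steps = N, trial_id = series$trial_id,
                 patient_id = series$patient_id, form = series$form),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> %s: 81 x 20 harmonic amplitudes (N = %d)\n",
              x$trial_id, x$n_steps))
  invisible(x)
}

#' Cut overlapping sequence windows from an angle series
#'
#' Sliding windows of 75 frames displaced by 15 frames, capped at 45
#' windows per trial; trailing frames that do not fill a window are
#' dropped. For `F` frames the window count is
#' `min(45, floor((F - 75) / 15) + 1)`.
#'
#' @param series an [angle_series()] with at least 75 frames.
#' @param length_,stride,max_windows window geometry; defaults 75/15/45.
#' @return An object of class `window_set`: list with `windows` (list of
#'   `75 x 81` matrices), `starts` (0-based start frames), plus trial
#'   metadata.
#' @export
window_sequences <- function(series, length_ = 75L, stride = 15L,
                             max_windows = 45L) {
  stopifnot(inherits(series, "angle_series"))
  if (length_ < 1L || stride < 1L || max_windows < 1L)
    stop("window length, stride and cap must be positive")
  f <- nrow(series$values)
  if (f < length_)
    stop("trial too short for windowing: ", f, " frames < ", length_)
  n_win <- min(max_windows, (f - length_) %/% stride + 1L)
  starts <- (seq_len(n_win) - 1L) * stride
  windows <- lapply(starts, function(s)
    series$values[(s + 1L):(s + length_), , drop = FALSE])
  structure(list(windows = windows, starts = starts,
                 trial_id = series$trial_id, patient_id = series$patient_id,
                 form = series$form),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s: %d windows of %d x %d\n", x$trial_id,
              length(x$windows), nrow(x$windows[[1]]), ncol(x$windows[[1]])))
  invisible(x)
}

#' Flatten spectral features to a CSV row / write feature tables
#'
#' `spectral_vector()` flattens the 81 x 20 matrix row-major into a named
#' length-1620 vector (`<angle>.h<k>`), the input layout for the MLP and
#' SVM. `write_spectral_csv()` writes one row per trial.
#'
#' @param sf a [spectral_features()] object.
#' @return Named numeric vector of length 1620.
#' @export
spectral_vector <- function(sf) {
  stopifnot(inherits(sf, "spectral_features"))
  v <- as.numeric(t(sf$coeffs))
  names(v) <- paste0(rep(rownames(sf$coeffs), each = 20L), ".",
                     rep(colnames(sf$coeffs), times = 81L))
  v
}

#' @rdname spectral_vector
#' @param sfs list of `spectral_features`.
#' @param path output CSV path.
#' @export
write_spectral_csv <- function(sfs, path) {
  rows <- t(vapply(sfs, spectral_vector, numeric(1620L)))
  df <- data.frame(trial_id = vapply(sfs, `[[`, "", "trial_id"),
                   patient_id = vapply(sfs, `[[`, "", "patient_id"),
                   form = vapply(sfs, function(s) as.integer(s$form), 0L),
                   rows, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
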