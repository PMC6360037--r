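#' Gait events container
#'
#' Foot-strike and toe-off frame indices (0-based, matching fixture frame
#' numbering) per body side.
#'
#' @param left_strikes,right_strikes,left_toeoffs,right_toeoffs integer
#'   vectors of frame indices, strictly increasing within each vector.
#' @param n_frames number of frames of the trial the events refer to.
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(left_strikes, right_strikes,
                        left_toeoffs = integer(0),
                        right_toeoffs = integer(0), n_frames = Inf) {
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (is.unsorted(x, strictly = TRUE))
      stop(nm, " must be strictly increasing")
    if (length(x) && (min(x) < 0L || max(x) >= n_frames))
      stop(nm, " contains frame indices outside the trial")
    x
  }
  structure(list(
    left_strikes = chk(left_strikes, "left_strikes"),
    right_strikes = chk(right_strikes, "right_strikes"),
    left_toeoffs = chk(left_toeoffs, "left_toeoffs"),
    right_toeoffs = chk(right_toeoffs, "right_toeoffs")
  ), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>",
      length(x$left_strikes), "L /", length(x$right_strikes),
      "R strikes,", length(x$left_toeoffs), "L /",
      length(x$right_toeoffs), "R toe-offs\n")
  invisible(x)
}

#' Subsample a trial by an integer factor
#'
#' Keeps frames 0, `factor`, `2*factor`, ... and divides the frame rate by
#' `factor`. No interpolation or filtering is applied. The standard
#' pipeline subsamples 100 -> 50 frames/sec (factor 2) so that the input to
#' the classifiers is closer to what a clinician perceives by eye.
#'
#' @param trial a [gait_trial()].
#' @param factor positive integer decimation factor.
#' @return The subsampled `gait_trial`.
#' @export
subsample <- function(trial, factor) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(trial)
  keep <- seq(1L, n_frames(trial), by = factor)
  if (length(keep) < 2L)
    stop("subsampling by ", factor, " would leave fewer than 2 frames")
  gait_trial(trial$positions[keep, , , drop = FALSE],
             trial$frame_rate / factor,
             patient_id = trial$patient_id, form = trial$form,
             trial_id = trial$trial_id)
}

# local minima of x at least `sep` apart, restricted to the lower part of
# the signal's range; returns 1-based indices
.local_minima <- function(x, sep, depth_frac = 0.5) {
  n <- length(x)
  lo <- min(x); hi <- max(x)
  if (hi - lo < 1e-9) return(integer(0))
  thresh <- lo + depth_frac * (hi - lo)
  cand <- which(x <= thresh)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] <= x[cand - 1L] & x[cand] <= x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  # greedy non-maximum suppression by depth
  ord <- cand[order(x[cand])]
  keep <- integer(0)
  for (i in ord) if (!length(keep) || all(abs(keep - i) >= sep))
    keep <- c(keep, i)
  sort(keep)
}

# dominant oscillation period (frames) of a zero-meaned signal via the
# first prominent autocorrelation peak
.dominant_period <- function(x, min_lag = 5L) {
  x <- x - mean(x)
  if (sd(x) < 1e-9) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(length(x) - 2L, 400L),
                   plot = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  ok <- lags >= min_lag
  peaks <- which(ok & c(FALSE, diff(ac) > 0)[seq_along(ac)] &
                 c(diff(ac) < 0, FALSE))
  peaks <- peaks[ac[peaks] > 0.2]
  if (!length(peaks)) return(NA_real_)
  lags[peaks[1]]
}

#' Detect foot strikes and toe-offs from heel and toe markers
#'
#' An automatic proxy for manual event marking: foot strikes are placed at
#' local minima of the heel markers' (RCA/LCA) vertical coordinate that
#' coincide with near-zero forward heel velocity; toe-offs at the maximum
#' of the toe markers' (RFM/LFM) vertical acceleration following each
#' strike. Hand-annotated events can be supplied instead wherever a
#' `gait_events` object is accepted (see [read_events_csv()]).
#'
#' @param trial a [gait_trial()] containing at least two gait cycles of
#'   forward walking.
#' @return A [gait_events()] object (0-based frame indices).
#' @export
detect_gait_events <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  fr <- trial$frame_rate
  smooth5 <- function(x) {
    s <- stats::filter(x, rep(1 / 5, 5), sides = 2)
    s[is.na(s)] <- x[is.na(s)]
    as.numeric(s)
  }
  side_events <- function(heel, toe) {
    z <- smooth5(heel[, "z"])
    per <- .dominant_period(z)
    if (is.na(per)) return(NULL)
    sep <- max(3L, round(0.6 * per))
    cand <- .local_minima(z, sep)
    if (length(cand) < 2L) return(NULL)
    # the heel-height valley has a flat bottom (the heel stays low through
    # early stance): the strike is the valley's left edge, so walk each
    # minimum back to the earliest frame still within `delta` of it
    delta <- max(3, 0.04 * (max(z) - min(z)))
    cand <- vapply(cand, function(m) {
      j <- m
      while (j > 1L && z[j - 1L] <= z[m] + delta) j <- j - 1L
      j
    }, 0L)
    # an onset at (or smoothed into) the first frames has no observed
    # pre-strike descent: the strike happened before recording started
    cand <- unique(cand[cand > 4L])
    if (length(cand) < 2L) return(NULL)
    # keep onsets where the heel is nearly stationary in the direction of
    # progression (stance), rejecting swing-phase dips
    vx <- c(0, diff(smooth5(heel[, "x"]))) * fr
    vref <- stats::quantile(abs(vx), 0.9)
    strikes <- cand[abs(vx[cand]) < 0.35 * vref]
    if (length(strikes) < 2L) strikes <- cand
    az <- c(0, 0, diff(diff(toe[, "z"]))) * fr^2
    toeoffs <- integer(0)
    bounds <- c(strikes, length(z))
    for (k in seq_along(strikes)) {
      from <- strikes[k] + 3L
      to <- bounds[k + 1L] - 3L
      if (to > from) toeoffs <- c(toeoffs, from - 1L + which.max(az[from:to]))
    }
    list(strikes = strikes, toeoffs = toeoffs)
  }
  l <- side_events(marker_xyz(trial, "LCA"), marker_xyz(trial, "LFM"))
  r <- side_events(marker_xyz(trial, "RCA"), marker_xyz(trial, "RFM"))
  if (is.null(l) || is.null(r) ||
      length(l$strikes) < 2L || length(r$strikes) < 2L)
    stop("insufficient steps: fewer than 2 foot strikes detected on a side")
  gait_events(l$strikes - 1L, r$strikes - 1L,
              l$toeoffs - 1L, r$toeoffs - 1L, n_frames(trial))
}

#' Read hand-annotated gait events from a sidecar CSV
#'
#' Expected columns `side,event,frame` with `side` in `{left,right}`,
#' `event` in `{strike,toeoff}` and 0-based frame indices.
#'
#' @param path CSV path.
#' @param n_frames frame count of the trial the events belong to.
#' @return A [gait_events()] object.
#' @export
read_events_csv <- function(path, n_frames = Inf) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("side", "event", "frame")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns side,event,frame")
  pick <- function(s, e) sort(df$frame[df$side == s & df$event == e])
  gait_events(pick("left", "strike"), pick("right", "strike"),
              pick("left", "toeoff"), pick("right", "toeoff"), n_frames)
}

#' Trim a trial to an integer number of steps
#'
#' Drops frames before the first and after the last detected foot strike so
#' that the retained span contains whole steps only. A step is the interval
#' between consecutive strikes of alternating feet, so a span delimited by
#' `k` strikes (both sides pooled) contains `k - 1` steps. The average step
#' period is the trimmed duration divided by the number of steps.
#'
#' @param trial a [gait_trial()].
#' @param events a [gait_events()] for `trial` (detected or hand-annotated).
#' @return A list with elements `trial` (the trimmed `gait_trial`) and
#'   `steps`, a `step_summary` list holding `n_steps` and `period_T`
#'   (seconds).
#' @export
trim_to_complete_steps <- function(trial, events) {
  stopifnot(inherits(trial, "gait_trial"), inherits(events, "gait_events"))
  strikes <- sort(c(events$left_strikes, events$right_strikes))
  if (length(strikes) < 2L)
    stop("insufficient steps: need at least 2 foot strikes to trim")
  d <- diff(strikes)
  med <- stats::median(d[d > 0])
  # drop near-duplicate strikes, then count steps per interval relative to
  # the median step interval so that a missed strike still counts 2 steps
  strikes <- strikes[c(TRUE, d >= 0.5 * med)]
  d <- diff(strikes)
  first <- strikes[1]; last <- strikes[length(strikes)]
  keep <- (first + 1L):(last + 1L)            # events are 0-based
  trimmed <- gait_trial(trial$positions[keep, , , drop = FALSE],
                        trial$frame_rate, patient_id = trial$patient_id,
                        form = trial$form, trial_id = trial$trial_id)
  n_steps <- if (length(d)) as.integer(sum(pmax(1, round(d / med)))) else 1L
  period_T <- (last - first) / trial$frame_rate / n_steps
  steps <- structure(list(n_steps = n_steps, period_T = period_T),
                     class = "step_summary")
  list(trial = trimmed, steps = steps)
}

#' @export
print.step_summary <- function(x, ...) {
  cat(sprintf("<step_summary> %d steps, T = %.3f s\n", x$n_steps, x$period_T))
  invisible(x)
}
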