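#' Default kinematic profiles of the four diplegic gait forms
#'
#' Phenomenological parameter presets whose distinguishing trait mirrors
#' the clinical description of each form: form 1 walks with a pronounced
#' forward trunk lean (antepulsion) and on the forefoot; form 2 with
#' pronounced stance knee flexion (crouch) and short steps; form 3 with a
#' large frontal trunk sway; form 4 with a marked equinus (plantarflexed
#' ankle) but otherwise the richest, most normal gait. Magnitudes are
#' declared simulator defaults, not measured clinical values.
#'
#' @return Named list (`"1"`..`"4"`) of `form_profile` lists with fields
#'   `trunk_antepulsion` (deg), `knee_flexion_offset` (deg, stance crouch),
#'   `stride_length` (mm), `frontal_sway` (deg), `equinus` (deg),
#'   `period_mean` and `period_sd` (s, step period).
#' @export
default_profiles <- function() {
  pf <- function(ante, knee, stride, sway, equinus, pm, psd)
    structure(list(trunk_antepulsion = ante, knee_flexion_offset = knee,
                   stride_length = stride, frontal_sway = sway,
                   equinus = equinus, period_mean = pm, period_sd = psd),
              class = "form_profile")
  list(`1` = pf(20, 6, 420, 3, 12, 1.05, 0.06),
       `2` = pf(5, 25, 300, 3, 5, 1.10, 0.06),
       `3` = pf(5, 8, 430, 15, 5, 1.00, 0.06),
       `4` = pf(1, 4, 480, 2, 20, 0.95, 0.06))
}

#' Draw a synthetic patient
#'
#' Per-patient random effects (one draw per parameter, bounded so that the
#' profile invariants still hold) model between-patient variability within
#' a form; leg segment lengths vary per patient as well.
#'
#' @param patient_id identifier string.
#' @param form integer form 1..4.
#' @param profile a `form_profile` (defaults to [default_profiles()] for
#'   `form`).
#' @return A `synth_patient` list: form, perturbed profile, segment
#'   lengths, and the patient's own step period.
#' @export
synth_patient <- function(patient_id, form, profile = NULL) {
  if (is.null(profile)) profile <- default_profiles()[[as.character(form)]]
  rb <- function(mu, sd, lo, hi) min(hi, max(lo, stats::rnorm(1, mu, sd)))
  p <- profile
  p$trunk_antepulsion <- rb(p$trunk_antepulsion, 1.5, -45, 45)
  p$knee_flexion_offset <- rb(p$knee_flexion_offset, 2, 0, 40)
  p$stride_length <- rb(p$stride_length, 20, 200, 520)
  p$frontal_sway <- rb(p$frontal_sway, 1.2, 0, 30)
  p$equinus <- rb(p$equinus, 1.5, 0, 35)
  period <- rb(p$period_mean, p$period_sd, 0.6, 1.8)
  structure(list(patient_id = patient_id, form = as.integer(form),
                 profile = p, period = period,
                 thigh = rb(400, 15, 350, 450),
                 shank = rb(360, 12, 320, 410),
                 trunk_len = rb(450, 20, 380, 520)),
            class = "synth_patient")
}

# rotation matrices (world axes: x anterior, y left, z up)
.rx <- function(b) matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3)
.ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)

#' Generate one synthetic walking trial
#'
#' A kinematic-chain walker: the pelvis translates at `stride / (2T)` with
#' small vertical and lateral oscillations; each foot alternates a 60%
#' stance (fixed on the ground) with a smooth swing; knees are placed by
#' two-link inverse kinematics from hip to ankle; heel and toe markers
#' follow a foot-pitch program (equinus offset plus progressive heel rise
#' through stance, so the heel height has a unique minimum at each foot
#' strike); the trunk pitches forward by the antepulsion angle and sways
#' laterally at step frequency; shoulders and arms swing in anti-phase with
#' the legs. Scripted foot-strike/toe-off frames are returned as ground
#' truth. Fully deterministic under `seed`.
#'
#' @param patient a [synth_patient()].
#' @param duration trial length in seconds (must contain >= 2 steps).
#' @param frame_rate frames per second (default 100, the acquisition rate).
#' @param noise_sd additive Gaussian marker noise, mm per coordinate.
#' @param seed integer seed.
#' @param trial_id optional identifier.
#' @return List with `trial` (a [gait_trial()]) and `events` (ground-truth
#'   [gait_events()], 0-based frames).
#' @export
generate_trial <- function(patient, duration, frame_rate = 100,
                           noise_sd = 1, seed = 1L, trial_id = NULL) {
  stopifnot(inherits(patient, "synth_patient"))
  p <- patient$profile
  T_step <- patient$period
  if (duration < 2.5 * T_step)
    stop("duration too short: need at least ~2 steps (", 2.5 * T_step, " s)")
  set.seed(as.integer(seed))
  nf <- as.integer(round(duration * frame_rate))
  # random start phase so trials begin mid-step (partial steps at the ends)
  t0 <- stats::runif(1, 0, 2 * T_step)
  tt <- t0 + (seq_len(nf) - 1L) / frame_rate

  stride <- p$stride_length
  T_stride <- 2 * T_step
  speed <- stride / T_stride
  stance_frac <- 0.6
  l1 <- patient$thigh; l2 <- patient$shank
  crouch <- cos((p$knee_flexion_offset / 2) * pi / 180)
  pelvis_h <- 0.93 * (l1 + l2) * crouch
  ankle_h <- 70
  lift <- 60
  hip_halfw <- 90

  # pelvis centre
  xp <- speed * tt
  yp <- 18 * sin(2 * pi * tt / T_stride)
  zp <- pelvis_h + 12 * cos(4 * pi * tt / T_stride)

  mk <- array(NA_real_, c(nf, 19L, 3L),
              dimnames = list(NULL, .GAIT_MARKERS, c("x", "y", "z")))

  leg <- function(phase_off, side_sign) {
    # side_sign: +1 left (y positive), -1 right
    phi <- ((tt / T_stride) + phase_off) %% 1
    cycle <- floor(tt / T_stride + phase_off)
    x_contact <- (cycle - phase_off) * stride + stride * 0.25
    in_stance <- phi < stance_frac
    s_st <- phi / stance_frac
    s_sw <- (phi - stance_frac) / (1 - stance_frac)
    xa <- ifelse(in_stance, x_contact,
                 x_contact + stride * 0.5 * (1 - cos(pi * s_sw)))
    za <- ifelse(in_stance, ankle_h, ankle_h + lift * sin(pi * s_sw))
    ya <- yp * 0.3 + side_sign * hip_halfw
    # hip joint
    xh <- xp; zh <- zp; yh <- yp + side_sign * hip_halfw
    # two-link IK in the leg's parasagittal plane
    dx <- xa - xh; dz <- za - zh
    d <- sqrt(dx^2 + dz^2)
    d <- pmin(pmax(d, abs(l1 - l2) + 1), l1 + l2 - 1)
    a1 <- (l1^2 - l2^2 + d^2) / (2 * d)
    h <- sqrt(pmax(l1^2 - a1^2, 0))
    ux <- dx / d; uz <- dz / d
    xk <- xh + a1 * ux - h * uz          # knee anterior of the hip-ankle line
    zk <- zh + a1 * uz + h * ux
    yk <- (yh + ya) / 2
    # foot pitch: equinus offset + heel rise through stance
    theta <- (p$equinus + 28 * ifelse(in_stance, s_st^2, (1 - s_sw)^2)) *
      pi / 180
    foot_pt <- function(vx, vz) {
      cbind(x = xa + vx * cos(theta) + vz * sin(theta),
            z = za - vx * sin(theta) + vz * cos(theta))
    }
    heel <- foot_pt(-60, -30)
    toe <- foot_pt(130, -45)
    list(gt = cbind(xh, yh + side_sign * 35, zh - 55),
         le = cbind(xk, yk + side_sign * 45, zk),
         ca = cbind(heel[, "x"], ya + side_sign * 8, heel[, "z"]),
         fm = cbind(toe[, "x"], ya + side_sign * 25, toe[, "z"]))
  }
  L <- leg(0.5, +1)
  R <- leg(0.0, -1)
  mk[, "LGT", ] <- L$gt; mk[, "RGT", ] <- R$gt
  mk[, "LLE", ] <- L$le; mk[, "RLE", ] <- R$le
  mk[, "LCA", ] <- L$ca; mk[, "RCA", ] <- R$ca
  mk[, "LFM", ] <- L$fm; mk[, "RFM", ] <- R$fm

  # pelvis markers (translation only; pelvis kept level)
  pel <- function(ox, oy, oz) cbind(xp + ox, yp + oy, zp + oz)
  mk[, "LASIS", ] <- pel(85, 115, 20);  mk[, "RASIS", ] <- pel(85, -115, 20)
  mk[, "LPSIS", ] <- pel(-85, 45, 35);  mk[, "RPSIS", ] <- pel(-85, -45, 35)

  # trunk + arms: pitch by antepulsion, sway at step frequency
  alpha <- p$trunk_antepulsion * pi / 180
  beta <- p$frontal_sway * pi / 180 * sin(2 * pi * tt / T_step)
  arm_amp <- 18 * pi / 180
  gamL <- arm_amp * sin(2 * pi * tt / T_stride)        # anti-phase w/ left leg
  gamR <- -gamL
  Lt <- patient$trunk_len
  trunk_pt <- function(off_fun) {
    out <- matrix(NA_real_, nf, 3)
    for (i in seq_len(nf)) {
      Rm <- .rx(beta[i]) %*% .ry(alpha)
      out[i, ] <- c(xp[i], yp[i], zp[i]) + as.numeric(Rm %*% off_fun(i))
    }
    out
  }
  mk[, "C7", ] <- trunk_pt(function(i) c(0, 0, Lt))
  mk[, "LA", ] <- trunk_pt(function(i) c(0, 170, Lt - 30))
  mk[, "RA", ] <- trunk_pt(function(i) c(0, -170, Lt - 30))
  arm <- function(sh_y, gam) {
    ep <- trunk_pt(function(i)
      c(280 * sin(gam[i]), sh_y, Lt - 30 - 280 * cos(gam[i])))
    ul <- trunk_pt(function(i)
      c(280 * sin(gam[i]) + 250 * sin(gam[i] + 0.45), sh_y * 1.02,
        Lt - 30 - 280 * cos(gam[i]) - 250 * cos(gam[i] + 0.45)))
    list(ep = ep, ul = ul)
  }
  la <- arm(185, gamL); ra <- arm(-185, gamR)
  mk[, "LEP", ] <- la$ep; mk[, "LUL", ] <- la$ul
  mk[, "REP", ] <- ra$ep; mk[, "RUL", ] <- ra$ul

  if (noise_sd > 0)
    mk <- mk + array(stats::rnorm(length(mk), 0, noise_sd), dim(mk))

  # scripted ground-truth events: strike at phase 0, toe-off at stance end
  ev_times <- function(phase_off) {
    k <- seq(ceiling(t0 / T_stride + phase_off),
             floor((t0 + duration) / T_stride + phase_off))
    strikes <- (k - phase_off) * T_stride
    toeoffs <- strikes + stance_frac * T_stride
    list(st = strikes[strikes >= t0 & strikes <= tt[nf]],
         to = toeoffs[toeoffs >= t0 & toeoffs <= tt[nf]])
  }
  evL <- ev_times(0.5); evR <- ev_times(0.0)
  to_frame <- function(x) as.integer(round((x - t0) * frame_rate))
  trial <- gait_trial(mk, frame_rate, patient_id = patient$patient_id,
                      form = patient$form,
                      trial_id = trial_id %||%
                        paste0(patient$patient_id, "-t", seed))
  events <- gait_events(to_frame(evL$st), to_frame(evR$st),
                        to_frame(evL$to), to_frame(evR$to), nf)
  list(trial = trial, events = events)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_per_form[f]` patients of each form (with per-patient random
#' effects) and `trials_per_patient` trials each. The default per-form
#' patient counts mirror the uneven clinical prevalence of the four forms
#' (13, 49, 34, 78 scaled down by 1/3).
#'
#' @param n_per_form integer vector of length 4: patients per form.
#' @param trials_per_patient trials per patient.
#' @param seed integer master seed; every trial seed derives from it.
#' @param duration,frame_rate,noise_sd forwarded to [generate_trial()].
#' @param profiles optional named list of `form_profile` overrides.
#' @return A `gait_dataset` list: `trials` (list of [gait_trial()]),
#'   `truth_events` (parallel list of [gait_events()]), `patients`
#'   (data.frame patient_id/form).
#' @export
generate_dataset <- function(n_per_form = c(5, 17, 12, 26),
                             trials_per_patient = 3L, seed = 1L,
                             duration = 8, frame_rate = 100, noise_sd = 1,
                             profiles = default_profiles()) {
  stopifnot(length(n_per_form) == 4L, all(n_per_form >= 1L),
            trials_per_patient >= 1L)
  set.seed(as.integer(seed))
  trials <- list(); truth <- list()
  pts <- data.frame(patient_id = character(0), form = integer(0))
  for (f in 1:4) {
    for (i in seq_len(n_per_form[f])) {
      pid <- sprintf("F%dP%02d", f, i)
      pat <- synth_patient(pid, f, profiles[[as.character(f)]])
      pts <- rbind(pts, data.frame(patient_id = pid, form = f))
      for (k in seq_len(trials_per_patient)) {
        s <- sample.int(.Machine$integer.max - 1L, 1L)
        g <- generate_trial(pat, duration, frame_rate, noise_sd, seed = s,
                            trial_id = sprintf("%s-w%d", pid, k))
        trials[[length(trials) + 1L]] <- g$trial
        truth[[length(truth) + 1L]] <- g$events
      }
    }
  }
  structure(list(trials = trials, truth_events = truth, patients = pts),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  tab <- table(factor(vapply(x$trials, `[[`, 0L, "form"), levels = 1:4))
  cat("<gait_dataset>", length(x$trials), "trials,",
      nrow(x$patients), "patients; trials per form:",
      paste(tab, collapse = "/"), "\n")
  invisible(x)
}
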