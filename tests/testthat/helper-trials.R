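# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures are stored.

# a structurally valid trial with smooth pseudo-random marker motion
random_trial <- function(nf = 20L, frame_rate = 100, seed = 1L,
                         patient_id = "P1", form = 2L) {
  set.seed(seed)
  pos <- array(NA_real_, c(nf, 19L, 3L),
               dimnames = list(NULL, gait_markers(), c("x", "y", "z")))
  tt <- seq_len(nf) / frame_rate
  for (m in seq_len(19L)) for (k in 1:3) {
    pos[, m, k] <- stats::rnorm(1, 0, 500) +
      stats::rnorm(1, 0, 100) * sin(2 * pi * stats::runif(1, 0.5, 2) * tt) +
      stats::rnorm(nf, 0, 2)
  }
  gait_trial(pos, frame_rate, patient_id = patient_id, form = form,
             trial_id = paste0(patient_id, "-r", seed))
}

# a motionless (standing) trial
standing_trial <- function(nf = 300L, frame_rate = 50) {
  pos <- array(rep(seq(100, 1900, length.out = 19L * 3L), each = nf),
               c(nf, 19L, 3L),
               dimnames = list(NULL, gait_markers(), c("x", "y", "z")))
  gait_trial(pos, frame_rate, patient_id = "still", form = 1L)
}

# an angle_series with given frame count / step count, values in [0, 180]
random_series <- function(nf, n_steps, seed = 1L) {
  set.seed(seed)
  vals <- matrix(stats::runif(nf * 81L, 0, 180), nf, 81L)
  colnames(vals) <- angle_feature_names()
  structure(list(values = vals, frame_rate = 50, n_steps = n_steps,
                 trial_id = "synthetic-series", patient_id = "PX",
                 form = 1L),
            class = "angle_series")
}

# a synthetic patient with an exact step period (for scripted-event tests)
patient_with_period <- function(period, form = 4L, seed = 1L) {
  set.seed(seed)
  pat <- synth_patient(sprintf("per%.2f", period), form)
  pat$period <- period
  pat
}

# brute-force O(n^2) DFT magnitude at one frequency index (the oracle in
# spectral tests; deliberately independent of stats::fft)
dft_mag <- function(x, k) {
  n <- length(x)
  Mod(sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n)))
}
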