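test_that("plane projections drop the orthogonal coordinate", {
  p <- c(1, 2, 3)
  expect_equal(project_to_plane(p, "sagittal"), c(1, 3))
  expect_equal(project_to_plane(p, "frontal"), c(2, 3))
  expect_equal(project_to_plane(p, "transverse"), c(1, 2))
  expect_error(project_to_plane(p, "axial"), "unknown plane")
  m <- matrix(1:6, 2)
  expect_equal(project_to_plane(m, "frontal"), m[, 2:3])
})

test_that("triplet angles match the law-of-cosines oracle", {
  expect_equal(triplet_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(triplet_angle(c(1, 0), c(0, 0), c(-1, 0)), 180)
  expect_error(triplet_angle(c(0, 0), c(0, 0), c(1, 1)), "degenerate")

  set.seed(6)
  n <- 10000L
  p1 <- matrix(rnorm(2 * n, 0, 100), n)
  vx <- matrix(rnorm(2 * n, 0, 100), n)
  p3 <- matrix(rnorm(2 * n, 0, 100), n)
  got <- triplet_angle(p1, vx, p3)
  # oracle: angle from side lengths via the law of cosines
  a <- sqrt(rowSums((p1 - vx)^2))
  b <- sqrt(rowSums((p3 - vx)^2))
  cc <- sqrt(rowSums((p1 - p3)^2))
  oracle <- acos(pmin(1, pmax(-1, (a^2 + b^2 - cc^2) / (2 * a * b)))) *
    180 / pi
  expect_lt(max(abs(got - oracle)), 1e-9)
  expect_true(all(got >= 0 & got <= 180))
})

test_that("angle extraction is invariant to rigid translation and scaling", {
  tr <- random_trial(nf = 10L, seed = 11L)
  base <- angle_series(tr)$values
  for (seed in 1:5) {
    set.seed(seed)
    shift <- rnorm(3, 0, 1000)
    scale <- runif(1, 0.2, 5)
    pos <- tr$positions
    for (k in 1:3) pos[, , k] <- (pos[, , k] + shift[k]) * scale
    moved <- gait_trial(pos, tr$frame_rate)
    expect_equal(angle_series(moved)$values, base, tolerance = 1e-9)
  }
})

test_that("a hand-placed 60-degree sagittal knee triplet is recovered", {
  tr <- random_trial(nf = 2L, seed = 12L)
  pos <- tr$positions
  # triplet 1 is (LGT, LPSIS, LLE) with vertex LPSIS; build a 60-degree
  # angle in the sagittal (x, z) projection, y arbitrary
  pos[, "LPSIS", ] <- rep(c(0, 123, 0), each = 2)
  pos[, "LGT", ] <- rep(c(500, -40, 0), each = 2)
  pos[, "LLE", ] <- rep(c(500 * cos(pi / 3), 77, 500 * sin(pi / 3)),
                        each = 2)
  got <- angle_series(gait_trial(pos, 100))$values
  expect_equal(unname(got[1, 1]), 60, tolerance = 1e-6)
  expect_identical(colnames(got)[1], "sagittal.LPSIS.LGT_LLE")
  expect_identical(ncol(got), 81L)
})

test_that("spectral features select step harmonics and normalize them", {
  # constant series: DC magnitude only, no harmonics
  s <- random_series(nf = 80L, n_steps = 2L)
  s$values[] <- rep(seq(10, 170, length.out = 81L), each = 80L)
  expect_warning(sf <- spectral_features(s), "vanishing fundamental")
  expect_equal(dim(sf$coeffs), c(81L, 20L))
  expect_equal(sf$coeffs[, 1], 80 * seq(10, 170, length.out = 81L),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(abs(sf$coeffs[, 2:20])), 0)

  # pure cosine at the step frequency with N = 4 steps
  s2 <- random_series(nf = 120L, n_steps = 4L)
  tt <- seq_len(120L) - 1L
  s2$values[] <- 90 + 30 * cos(2 * pi * 4 * tt / 120)
  sf2 <- spectral_features(s2)
  expect_equal(unname(sf2$coeffs[, 2]), rep(1, 81L))
  expect_lt(max(abs(sf2$coeffs[, 3:20])), 1e-9)
})

test_that("spectral features equal a brute-force DFT oracle", {
  for (N in c(1L, 2L, 3L, 5L)) {
    s <- random_series(nf = 30L * N, n_steps = N, seed = N)
    sf <- spectral_features(s)
    for (a in c(1L, 40L, 81L)) {
      mags <- vapply(0:19, function(h) dft_mag(s$values[, a], h * N),
                     numeric(1))
      expected <- c(mags[1], mags[-1] / mags[2])
      expect_lt(max(abs(sf$coeffs[a, ] - expected)), 1e-9)
    }
  }
})

test_that("spectral amplitudes are invariant to time reversal", {
  s <- random_series(nf = 90L, n_steps = 3L, seed = 8L)
  rev_s <- s
  rev_s$values <- s$values[rev(seq_len(nrow(s$values))), , drop = FALSE]
  expect_equal(spectral_features(rev_s)$coeffs, spectral_features(s)$coeffs,
               tolerance = 1e-9)
})

test_that("degenerate fundamentals zero-fill instead of failing the trial", {
  s <- random_series(nf = 60L, n_steps = 2L)
  s$values[, 5] <- 42                      # flat angle: no fundamental
  expect_warning(sf <- spectral_features(s), "vanishing fundamental")
  expect_equal(unname(sf$coeffs[5, ]), c(60 * 42, rep(0, 19L)))
  expect_true(all(is.finite(sf$coeffs)))
})

test_that("window counts follow min(45, floor((F - 75) / 15) + 1)", {
  cases <- list(c(75L, 1L), c(76L, 1L), c(90L, 2L), c(735L, 45L),
                c(800L, 45L), c(2000L, 45L))
  for (cs in cases) {
    ws <- window_sequences(random_series(nf = cs[1], n_steps = 3L))
    expect_identical(length(ws$windows), cs[2])
    expect_equal(ws$starts, seq(0L, by = 15L, length.out = cs[2]))
  }
  expect_error(window_sequences(random_series(nf = 74L, n_steps = 3L)),
               "too short")
})

test_that("windows are exact slices of the angle series", {
  s <- random_series(nf = 120L, n_steps = 3L, seed = 9L)
  ws <- window_sequences(s)
  expect_identical(length(ws$windows), 4L)
  for (i in seq_along(ws$windows)) {
    st <- ws$starts[i]
    expect_identical(ws$windows[[i]],
                     s$values[(st + 1L):(st + 75L), , drop = FALSE])
  }
})
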