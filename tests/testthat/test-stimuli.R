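test_that("a zero-update-rate grating is static", {
  spec <- small_spec(wavelength_deg = 90, motion_hz = 0,
                     polarity_mode = "phi")
  stim <- make_grating_stimulus(spec, 13)
  lum <- stim$luminance
  expect_true(all(apply(lum, 2, function(col) all(col == col[1]))))
  expect_true(all(lum %in% spec$luminance_levels))
})

test_that("grating columns stay on the three luminance levels and timing matches", {
  spec <- small_spec(wavelength_deg = 90, velocity_deg_s = 60,
                     polarity_mode = "reverse-phi")
  stim <- make_grating_stimulus(spec, 13, dt_s = 0.001)
  expect_true(all(stim$luminance %in% spec$luminance_levels))
  expect_equal(nrow(stim$luminance), round(spec$duration_s / 0.001))
  # displacement/reversal events occur every 1/15 s (66.7 ms): count the
  # time samples at which the pattern changes during motion
  changed <- which(rowSums(abs(diff(stim$luminance))) > 0)
  t_changes <- stimulus_times(stim)[changed + 1]
  in_motion <- t_changes > spec$motion_onset_s & t_changes <= spec$motion_offset_s
  expect_true(all(in_motion))
  expect_equal(length(t_changes),
               floor((spec$motion_offset_s - spec$motion_onset_s) * 15))
  expect_equal(diff(t_changes), rep(1 / 15, length(t_changes) - 1),
               tolerance = 0.05)
})

test_that("phi-dark and phi-bright are identical after swapping dark and bright", {
  sp_b <- small_spec(wavelength_deg = 90, velocity_deg_s = 64,
                     polarity_mode = "phi-bright")
  sp_d <- small_spec(wavelength_deg = 90, velocity_deg_s = 64,
                     polarity_mode = "phi-dark")
  a <- make_grating_stimulus(sp_b, 13)$luminance
  b <- make_grating_stimulus(sp_d, 13)$luminance
  lev <- sp_b$luminance_levels
  swapped <- a
  swapped[a == lev[3]] <- lev[1]
  swapped[a == lev[1]] <- lev[3]
  expect_identical(swapped, b)
})

test_that("default luminance triplet is symmetric about the gray level", {
  spec <- stimulus_spec(velocity_deg_s = 64)
  lev <- spec$luminance_levels
  expect_equal(lev[3] - lev[2], lev[2] - lev[1])
  # instantaneous Michelson contrast of non-gray vs gray stripes is
  # approximately equal for bright and dark states (the denominators
  # differ, so the match is only approximate)
  expect_equal((lev[3] - lev[2]) / (lev[3] + lev[2]),
               (lev[2] - lev[1]) / (lev[2] + lev[1]),
               tolerance = 0.25)
})

test_that("decoupled clocks reduce to phi and reverse-phi exactly", {
  # flicker 0 at motion 16 Hz == phi at v = 64 deg/s, step 4
  dec <- make_decoupled_stimulus(
    small_spec(motion_hz = 16, flicker_hz = 0, polarity_mode = "phi"), 13)
  phi <- make_grating_stimulus(
    small_spec(velocity_deg_s = 64, polarity_mode = "phi"), 13)
  expect_identical(dec$luminance, phi$luminance)
  # equal clocks at zero offset == reverse-phi at v = 32 deg/s
  dec2 <- make_decoupled_stimulus(
    small_spec(motion_hz = 8, flicker_hz = 8,
               polarity_mode = "reverse-phi"), 13)
  rp <- make_grating_stimulus(
    small_spec(velocity_deg_s = 32, polarity_mode = "reverse-phi"), 13)
  expect_identical(dec2$luminance, rp$luminance)
})

test_that("a half-period flicker offset places reversals midway between jumps", {
  spec <- small_spec(motion_hz = 4, flicker_hz = 4, phase_offset_frac = 0.5,
                     polarity_mode = "reverse-phi", wavelength_deg = 90)
  stim <- make_grating_stimulus(spec, 13, dt_s = 0.001)
  lum <- stim$luminance
  # a pattern change with unchanged value set = pure displacement; a
  # change where bright and dark swap everywhere = pure reversal
  changed <- which(rowSums(abs(diff(lum))) > 0)
  t_all <- stimulus_times(stim)
  kinds <- vapply(changed, function(i) {
    before <- lum[i, ]; after <- lum[i + 1, ]
    lev <- spec$luminance_levels
    flipped <- before
    flipped[before == lev[3]] <- lev[1]
    flipped[before == lev[1]] <- lev[3]
    if (identical(after, flipped)) "reversal" else "displacement"
  }, character(1))
  t_disp <- t_all[changed[kinds == "displacement"] + 1]
  t_flip <- t_all[changed[kinds == "reversal"] + 1]
  expect_gt(length(t_disp), 0)
  expect_gt(length(t_flip), 0)
  # reversals sit half an update period (125 ms) after displacements
  gaps <- vapply(t_flip, function(tf) min(abs(tf - t_disp)), numeric(1))
  expect_equal(gaps, rep(0.125, length(gaps)), tolerance = 0.02)
})

test_that("rightward and leftward gratings shift the pattern in opposite directions", {
  # commensurate layout: wavelength 32 deg over 16 receptors at 4 deg
  for (dir in c(1, -1)) {
    spec <- small_spec(wavelength_deg = 32, velocity_deg_s = 16,
                       polarity_mode = "phi", direction = dir)
    stim <- make_grating_stimulus(spec, 16, dt_s = 0.002)
    lum <- stim$luminance
    changed <- which(rowSums(abs(diff(lum))) > 0)
    i <- changed[2]
    before <- lum[i, ]; after <- lum[i + 1, ]
    # one step = 4 deg = 1 receptor; circular shift by the direction
    shifted <- if (dir == 1) c(before[16], before[1:15]) else c(before[2:16], before[1])
    expect_identical(after, shifted)
  }
})

test_that("translating noise is deterministic, static at v = 0, and directional", {
  a <- make_translating_noise(60, 20, 0.01, seed = 7)
  b <- make_translating_noise(60, 20, 0.01, seed = 7)
  expect_identical(a$luminance, b$luminance)
  c0 <- make_translating_noise(0, 20, 0.01, seed = 7)
  expect_true(all(apply(c0$luminance, 2, function(col) all(col == col[1]))))
  left <- make_translating_noise(-60, 20, 0.01, seed = 7)
  expect_equal(left$direction, -1)
  expect_error(make_translating_noise(60, 0, 0.01, seed = 7))
})

test_that("stimulus rectification obeys the half-wave identity", {
  stim <- random_stimulus()
  expect_equal(rectify_stimulus(stim, "ON")$luminance +
                 rectify_stimulus(stim, "OFF")$luminance -
                 mean(stim$luminance),
               stim$luminance)
  const <- spacetime_stimulus(matrix(1.3, 50, 5), 4, 0.002)
  expect_identical(rectify_stimulus(const, "ON")$luminance, const$luminance)
  expect_identical(rectify_stimulus(const, "OFF")$luminance, const$luminance)
})

test_that("temporal aliasing and invalid specs are rejected", {
  expect_error(make_grating_stimulus(
    small_spec(velocity_deg_s = 256, polarity_mode = "reverse-phi"),
    13, dt_s = 0.01), "aliasing")
  expect_error(stimulus_spec(velocity_deg_s = 64, motion_hz = 3),
               "motion_hz")
  expect_error(stimulus_spec(polarity_mode = "phi"), "velocity_deg_s|motion_hz")
  expect_error(make_decoupled_stimulus(
    small_spec(motion_hz = 8, flicker_hz = -2), 13))
})

test_that("stimuli round-trip through CSV export", {
  spec <- small_spec(wavelength_deg = 90, velocity_deg_s = 64,
                     polarity_mode = "reverse-phi")
  stim <- make_grating_stimulus(spec, 7, dt_s = 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stimulus_csv(stim, path)
  back <- read_stimulus_csv(path)
  expect_equal(back$luminance, stim$luminance)
  expect_equal(back$dt_s, stim$dt_s)
  expect_equal(back$spec$velocity_deg_s, spec$velocity_deg_s)
  expect_equal(back$spec$polarity_mode, spec$polarity_mode)
})
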