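test_that("four-quadrant output equals the signed sum of rectified quadrant products", {
  # oracle: rebuild the 4Q computation but expand every multiplication
  # u * v into u+ v+ + u- v- - u+ v- - u- v+ ; this pins the
  # "all four correlations" semantics and must agree to machine precision
  cfg <- small_config("4Q", n_detectors = 8)
  stim <- random_stimulus(nt = 500, nr = 9, dt = cfg$dt_s, seed = 9)
  out <- simulate_emd(stim, cfg)

  quad_mult <- function(u, v) {
    half_wave(u, "ON") * half_wave(v, "ON") +
      half_wave(u, "OFF") * half_wave(v, "OFF") -
      half_wave(u, "ON") * half_wave(v, "OFF") -
      half_wave(u, "OFF") * half_wave(v, "ON")
  }
  arm <- highpass(stim$luminance, cfg$tau_hp_s, cfg$dt_s)
  del <- lowpass(arm, cfg$tau_lp_s, cfg$dt_s)
  left <- 1:8; right <- 2:9
  per <- quad_mult(del[, left], arm[, right]) -
    quad_mult(arm[, left], del[, right])
  expect_identical(out$summed, rowSums(per))
})

test_that("static and zero-contrast stimuli produce null output", {
  cfg <- small_config("4Q")
  static <- make_grating_stimulus(
    small_spec(wavelength_deg = 90, motion_hz = 0, polarity_mode = "phi"),
    13, dt_s = cfg$dt_s)
  expect_equal(mean_response(simulate_emd(static, cfg)), 0)
  # uniform gray field: constant null output (no transient, since filter
  # states start at the first sample) up to floating-point residue
  gray <- spacetime_stimulus(matrix(1.3, 1500, 13), 4, cfg$dt_s)
  for (model in c("4Q", "2Q")) {
    out <- simulate_emd(gray, small_config(model))
    expect_lt(max(abs(out$summed)), 1e-12)
  }
})

test_that("mirrored stimuli give equal and opposite mean responses", {
  cfg <- detector_config("2Q", n_detectors = 30)
  spec <- stimulus_spec(wavelength_deg = 90, velocity_deg_s = 64,
                        polarity_mode = "phi", duration_s = 4,
                        motion_onset_s = 0.25, motion_offset_s = 3.75)
  stim <- make_grating_stimulus(spec, 31)
  r <- mean_response(simulate_emd(stim, cfg))
  r_m <- mean_response(simulate_emd(mirror_stimulus(stim), cfg))
  expect_equal(r_m, -r, tolerance = 0.05)
})

test_that("4Q steady-state response to a drifting sinusoid matches the closed form", {
  cfg <- detector_config("4Q", n_detectors = 20)
  lam <- 90; C <- 0.25
  for (ft in c(0.5, 2, 8)) {
    stim <- sinusoid_stimulus(ft, lam, 21, duration_s = 6, dt = cfg$dt_s,
                              contrast = C)
    out <- simulate_emd(stim, cfg)
    win <- out$time_s >= 2 & out$time_s < 2 + floor(3 * ft) / ft
    sim <- mean(out$summed[win])
    # independent oracle: discrete transfer functions of the Euler
    # filters and the stationary-phasor average of the correlator
    a_lp <- cfg$dt_s / cfg$tau_lp_s
    a_hp <- cfg$dt_s / cfg$tau_hp_s
    z <- exp(2i * pi * ft * cfg$dt_s)
    g_lp <- (a_lp / z) / (1 - (1 - a_lp) / z)
    h_hp <- 1 - (a_hp / z) / (1 - (1 - a_hp) / z)
    delta <- 2 * pi * cfg$receptor_spacing_deg / lam
    pred <- cfg$n_detectors * (-(C * Mod(h_hp))^2 * Im(g_lp) * sin(delta))
    expect_equal(sim, pred, tolerance = 0.05)
  }
})

test_that("without DC the 2Q and 4Q phi tunings agree in sign and rank order", {
  cfg2 <- detector_config("2Q", n_detectors = 20,
                          dc_frac_on = 0, dc_frac_off = 0)
  cfg4 <- detector_config("4Q", n_detectors = 20)
  vs <- default_velocity_grid(10, 4, 600)
  t2 <- velocity_tuning(cfg2, 90, "phi", vs, duration_s = 5,
                        motion_onset_s = 0.25, motion_offset_s = 4.75)
  t4 <- velocity_tuning(cfg4, 90, "phi", vs, duration_s = 5,
                        motion_onset_s = 0.25, motion_offset_s = 4.75)
  expect_true(all(sign(t2$response) == sign(t4$response)))
  expect_gt(cor(t2$response, t4$response, method = "spearman"), 0.9)
})

test_that("mean_response windows behave linearly and reject empty windows", {
  out <- structure(
    list(summed = rep(3.5, 100), time_s = (0:99) * 0.01,
         config = small_config(), stimulus_spec = NULL),
    class = "detector_output")
  expect_equal(mean_response(out, c(0, 1)), 3.5)
  # two half-windows recombine to the full-window mean
  out$summed <- withr::with_seed(8, rnorm(100))
  m1 <- mean_response(out, c(0, 0.3))
  m2 <- mean_response(out, c(0.3, 1.0))
  expect_equal((30 * m1 + 70 * m2) / 100, mean_response(out, c(0, 1)))
  expect_error(mean_response(out, c(2, 3)), "empty")
})

test_that("simulation rejects mismatched stimuli and honours DC arms", {
  cfg <- small_config("4Q")
  stim <- random_stimulus(nt = 100, nr = 5, dt = cfg$dt_s)
  expect_error(simulate_emd(stim, cfg), "receptors")
  stim2 <- random_stimulus(nt = 100, nr = 13, dt = 0.01)
  expect_error(simulate_emd(stim2, small_config("4Q")), "dt_s")
  cfg_bad <- small_config("4Q")
  cfg_bad$dc_frac_on <- 0.1
  expect_error(simulate_emd(random_stimulus(nt = 100, nr = 13,
                                            dt = cfg_bad$dt_s), cfg_bad),
               "equal")
  # the 4Q arm honours a nonzero DC fraction: responses change
  stim3 <- small_grating(small_spec(wavelength_deg = 90, velocity_deg_s = 64,
                                    polarity_mode = "reverse-phi"),
                         small_config("4Q"))
  r0 <- mean_response(simulate_emd(stim3, small_config("4Q")))
  rdc <- mean_response(simulate_emd(
    stim3, small_config("4Q", dc_frac_on = 0.1, dc_frac_off = 0.1)))
  expect_false(isTRUE(all.equal(r0, rdc)))
})

test_that("per-detector output sums to the array output and smoothing is gentle", {
  cfg <- small_config("2Q")
  stim <- small_grating(small_spec(wavelength_deg = 90, velocity_deg_s = 64,
                                   polarity_mode = "reverse-phi"), cfg)
  out <- simulate_emd(stim, cfg, keep_per_detector = TRUE)
  expect_equal(rowSums(out$per_detector), out$summed)
  tr <- smooth_display(out)
  expect_equal(nrow(tr), length(out$summed))
  # smoothing a constant series leaves it unchanged
  out$summed <- rep(1.25, length(out$summed))
  expect_equal(smooth_display(out)$response, rep(1.25, length(out$summed)))
})
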