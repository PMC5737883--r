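# Small, fast configurations for unit tests; acceptance tests use the
# full default parameter set.

small_config <- function(model = "2Q", n_detectors = 12, dt_s = 0.002, ...) {
  detector_config(model, n_detectors = n_detectors, dt_s = dt_s, ...)
}

small_spec <- function(...) {
  stimulus_spec(duration_s = 3, motion_onset_s = 0.25,
                motion_offset_s = 2.75, ...)
}

small_grating <- function(spec, cfg) {
  make_grating_stimulus(spec, cfg$n_detectors + 1,
                        cfg$receptor_spacing_deg, cfg$dt_s)
}

# Random-luminance stimulus (values in a positive band, like gratings)
random_stimulus <- function(nt = 400, nr = 9, dt = 0.002, spacing = 4,
                            seed = 1) {
  lum <- withr::with_seed(seed, matrix(runif(nt * nr, 1.0, 1.6), nt, nr))
  spacetime_stimulus(lum, spacing, dt)
}

# Drifting sinusoid with temporal frequency ft (Hz) and wavelength lam
# (deg); rightward for ft > 0.
sinusoid_stimulus <- function(ft, lam, n_receptors, duration_s, dt,
                              spacing = 4, contrast = 0.25, mean_lum = 1.3) {
  t <- seq(0, duration_s - dt, by = dt)
  x <- (seq_len(n_receptors) - 1) * spacing
  lum <- mean_lum + contrast * cos(2 * pi * outer(-ft * t, x / lam, `+`))
  spacetime_stimulus(lum, spacing, dt)
}
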