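#' Specify a discretized grating stimulus
#'
#' A stimulus specification collects every parameter needed to render a
#' one-dimensional, three-level square-wave grating as a space-time luminance
#' array. Gratings are composed of alternating "gray" stripes at an
#' intermediate luminance and "non-gray" stripes that are either dark or
#' bright depending on the current polarity state. During the motion
#' interval the pattern jumps by `step_deg` every `1 / motion_hz` seconds;
#' in reverse-phi mode the non-gray stripes additionally flip between dark
#' and bright at `flicker_hz`. Outside the motion interval the pattern is
#' frozen: no displacement and no contrast reversal occurs.
#'
#' Exactly one of `velocity_deg_s` and `motion_hz` must be given; the other
#' is derived through `v = motion_hz * step_deg`, the single unit conversion
#' used throughout the package. For `polarity_mode = "reverse-phi"`,
#' `flicker_hz` defaults to `motion_hz` (contrast reversal on every step);
#' for phi it is 0. `phase_offset_frac` shifts the flicker clock relative to
#' the displacement clock by a fraction of the update period, so 0.5 places
#' each contrast reversal midway between two displacements (the
#' "out-of-phase" control).
#'
#' @param wavelength_deg Spatial wavelength of the grating, degrees.
#' @param velocity_deg_s Pattern velocity, degrees/s. Mutually exclusive
#'   with `motion_hz`.
#' @param step_deg Spatial jump per motion update, degrees.
#' @param polarity_mode One of `"phi"`, `"reverse-phi"`. The shorthands
#'   `"phi-bright"` and `"phi-dark"` select phi with the corresponding
#'   initial polarity.
#' @param motion_hz Displacement update rate, Hz. Mutually exclusive with
#'   `velocity_deg_s`.
#' @param flicker_hz Contrast-reversal rate, Hz. Defaults to 0 for phi and
#'   to `motion_hz` for reverse-phi.
#' @param phase_offset_frac Phase of the flicker clock relative to the
#'   motion clock, as a fraction of the flicker period.
#' @param luminance_levels Numeric triplet `c(dark, mid, bright)` in
#'   arbitrary luminance units; must be strictly increasing.
#' @param duration_s Total stimulus duration, seconds.
#' @param motion_onset_s,motion_offset_s Motion interval bounds, seconds.
#' @param direction +1 for rightward (toward increasing azimuth), -1 for
#'   leftward.
#' @param initial_polarity `"bright"` or `"dark"`: the state of the
#'   non-gray stripes at stimulus onset. Experiments typically average over
#'   both.
#'
#' @return An object of class `stimulus_spec` (a named list).
#' @seealso [make_grating_stimulus()], [make_decoupled_stimulus()]
#' @export
#' @examples
#' stimulus_spec(wavelength_deg = 90, velocity_deg_s = 64,
#'               polarity_mode = "reverse-phi")
stimulus_spec <- function(wavelength_deg = 90,
                          velocity_deg_s = NULL,
                          step_deg = 4,
                          polarity_mode = c("phi", "reverse-phi",
                                            "phi-bright", "phi-dark"),
                          motion_hz = NULL,
                          flicker_hz = NULL,
                          phase_offset_frac = 0,
                          luminance_levels = c(1.05, 1.30, 1.55),
                          duration_s = 10,
                          motion_onset_s = 0.5,
                          motion_offset_s = 9.5,
                          direction = 1,
                          initial_polarity = c("bright", "dark")) {
  polarity_mode <- match.arg(polarity_mode)
  if (polarity_mode == "phi-bright") {
    polarity_mode <- "phi"; initial_polarity <- "bright"
  } else if (polarity_mode == "phi-dark") {
    polarity_mode <- "phi"; initial_polarity <- "dark"
  }
  initial_polarity <- match.arg(initial_polarity)

  if (is.null(velocity_deg_s) && is.null(motion_hz)) {
    stop("give either `velocity_deg_s` or `motion_hz`", call. = FALSE)
  }
  if (is.null(motion_hz)) motion_hz <- velocity_deg_s / step_deg
  if (is.null(velocity_deg_s)) velocity_deg_s <- motion_hz * step_deg
  if (abs(velocity_deg_s - motion_hz * step_deg) > 1e-9 * max(1, abs(velocity_deg_s))) {
    stop("`velocity_deg_s` must equal `motion_hz * step_deg`", call. = FALSE)
  }
  if (is.null(flicker_hz)) {
    flicker_hz <- if (polarity_mode == "reverse-phi") motion_hz else 0
  }

  stopifnot(
    wavelength_deg > 0, step_deg > 0,
    length(luminance_levels) == 3,
    luminance_levels[1] < luminance_levels[2],
    luminance_levels[2] < luminance_levels[3],
    motion_hz >= 0, flicker_hz >= 0,
    motion_onset_s < motion_offset_s, motion_offset_s <= duration_s,
    direction %in% c(-1, 1)
  )

  structure(
    list(
      wavelength_deg = wavelength_deg,
      velocity_deg_s = velocity_deg_s,
      step_deg = step_deg,
      polarity_mode = polarity_mode,
      motion_hz = motion_hz,
      flicker_hz = flicker_hz,
      phase_offset_frac = phase_offset_frac,
      luminance_levels = luminance_levels,
      duration_s = duration_s,
      motion_onset_s = motion_onset_s,
      motion_offset_s = motion_offset_s,
      direction = direction,
      initial_polarity = initial_polarity
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %s  lambda=%g deg  v=%g deg/s  step=%g deg\n",
    x$polarity_mode, x$wavelength_deg, x$velocity_deg_s, x$step_deg
  ))
  cat(sprintf(
    "  motion %g Hz, flicker %g Hz (phase offset %g), direction %+d, start %s\n",
    x$motion_hz, x$flicker_hz, x$phase_offset_frac, x$direction,
    x$initial_polarity
  ))
  cat(sprintf(
    "  duration %g s, motion on [%g, %g) s, luminance %s\n",
    x$duration_s, x$motion_onset_s, x$motion_offset_s,
    paste(x$luminance_levels, collapse = "/")
  ))
  invisible(x)
}

#' Construct a space-time stimulus from raw values
#'
#' Low-level constructor wrapping a luminance matrix (rows = time samples,
#' columns = receptor positions) with its sampling metadata. Receptor `i`
#' (0-based) sits at azimuth `i * receptor_spacing_deg`; time sample `n`
#' (1-based row) is at `(n - 1) * dt_s`, covering the half-open interval
#' `[0, duration)`.
#'
#' @param luminance Numeric matrix, time samples by receptors.
#' @param receptor_spacing_deg Receptor spacing, degrees.
#' @param dt_s Sampling interval, seconds.
#' @param spec Optional originating [stimulus_spec()].
#' @param direction Nominal motion direction (+1/-1); defaults to the
#'   spec's direction or +1.
#' @return An object of class `spacetime_stimulus`.
#' @export
spacetime_stimulus <- function(luminance, receptor_spacing_deg, dt_s,
                               spec = NULL, direction = NULL) {
  stopifnot(is.matrix(luminance), is.numeric(luminance),
            receptor_spacing_deg > 0, dt_s > 0)
  if (is.null(direction)) {
    direction <- if (!is.null(spec)) spec$direction else 1
  }
  structure(
    list(
      luminance = luminance,
      receptor_spacing_deg = receptor_spacing_deg,
      dt_s = dt_s,
      spec = spec,
      direction = direction
    ),
    class = "spacetime_stimulus"
  )
}

#' @export
print.spacetime_stimulus <- function(x, ...) {
  cat(sprintf(
    "<spacetime_stimulus> %d receptors (spacing %g deg) x %d samples (dt %g s)\n",
    ncol(x$luminance), x$receptor_spacing_deg, nrow(x$luminance), x$dt_s
  ))
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}

#' Time and position axes of a space-time stimulus
#'
#' @param stim A `spacetime_stimulus`.
#' @return Numeric vector of sample times (s) or receptor azimuths (deg).
#' @export
stimulus_times <- function(stim) {
  (seq_len(nrow(stim$luminance)) - 1) * stim$dt_s
}

#' @rdname stimulus_times
#' @export
stimulus_positions <- function(stim) {
  (seq_len(ncol(stim$luminance)) - 1) * stim$receptor_spacing_deg
}

#' @exportS3Method tibble::as_tibble
as_tibble.spacetime_stimulus <- function(x, ...) {
  tibble::tibble(
    receptor = rep(seq_len(ncol(x$luminance)) - 1L,
                   each = nrow(x$luminance)),
    position_deg = rep(stimulus_positions(x), each = nrow(x$luminance)),
    time_s = rep(stimulus_times(x), ncol(x$luminance)),
    luminance = as.vector(x$luminance)
  )
}

# Shared renderer for all discretized gratings. Displacement events occur at
# motion_onset + k / motion_hz (k = 1, 2, ...); contrast reversals at
# motion_onset + (k + phase_offset_frac) / flicker_hz. Both clocks are gated
# by the motion interval: the pattern is frozen in its initial state before
# onset and in its final state after offset.
render_grating <- function(spec, n_receptors, receptor_spacing_deg, dt_s) {
  stopifnot(n_receptors >= 2, dt_s > 0)
  for (f in c(spec$motion_hz, spec$flicker_hz)) {
    if (f > 0 && dt_s > 0.5 / f) {
      stop(sprintf(
        "dt_s = %g s exceeds half the update interval of a %g Hz clock (temporal aliasing)",
        dt_s, f
      ), call. = FALSE)
    }
  }
  nt <- round(spec$duration_s / dt_s)
  t <- (seq_len(nt) - 1) * dt_s
  x <- (seq_len(n_receptors) - 1) * receptor_spacing_deg

  # time elapsed inside the motion interval, clamped
  rel <- pmin(pmax(t - spec$motion_onset_s, 0),
              spec$motion_offset_s - spec$motion_onset_s)
  eps <- 1e-9
  n_jump <- if (spec$motion_hz > 0) floor(rel * spec$motion_hz + eps) else rep(0, nt)
  offset <- spec$direction * n_jump * spec$step_deg
  n_flip <- if (spec$flicker_hz > 0) {
    pmax(0, floor(rel * spec$flicker_hz - spec$phase_offset_frac + eps))
  } else {
    rep(0, nt)
  }

  start_bright <- spec$initial_polarity == "bright"
  bright_now <- xor(start_bright, n_flip %% 2 == 1)
  if (length(bright_now) == 1) bright_now <- rep(bright_now, nt)

  # pattern phase: stripe boundary at azimuth 0, tracked continuously
  phase <- (outer(-offset, x, `+`) %% spec$wavelength_deg) / spec$wavelength_deg
  nongray <- phase < 0.5

  lev <- spec$luminance_levels
  lum <- matrix(lev[2], nt, n_receptors)
  bright_m <- matrix(bright_now, nt, n_receptors)
  lum[nongray & bright_m] <- lev[3]
  lum[nongray & !bright_m] <- lev[1]

  spacetime_stimulus(lum, receptor_spacing_deg, dt_s, spec = spec)
}

#' Render a discretized phi or reverse-phi grating
#'
#' Produces the space-time luminance array for a square-wave grating of
#' period `wavelength_deg`: half of each period at the intermediate "gray"
#' level, the other half dark or bright according to the current polarity
#' state. During the motion interval the pattern displaces by `step_deg`
#' every `1 / motion_hz` seconds in the spec's direction; in reverse-phi
#' mode non-gray stripes flip between dark and bright at `flicker_hz`
#' (synchronized with displacement when `flicker_hz == motion_hz` and the
#' phase offset is zero). Before motion onset and after motion offset the
#' pattern is static.
#'
#' @param spec A [stimulus_spec()].
#' @param n_receptors Number of receptor columns to render (>= 2). Detector
#'   arrays with `n` detectors need `n + 1` receptors.
#' @param receptor_spacing_deg Receptor spacing, degrees.
#' @param dt_s Time step, seconds. Rejected when larger than half of any
#'   active update interval (temporal aliasing).
#' @return A [spacetime_stimulus()].
#' @export
#' @examples
#' spec <- stimulus_spec(wavelength_deg = 90, velocity_deg_s = 64,
#'                       polarity_mode = "reverse-phi", duration_s = 2,
#'                       motion_onset_s = 0.25, motion_offset_s = 1.75)
#' stim <- make_grating_stimulus(spec, n_receptors = 61)
make_grating_stimulus <- function(spec, n_receptors,
                                  receptor_spacing_deg = 4, dt_s = 0.001) {
  stopifnot(inherits(spec, "stimulus_spec"))
  render_grating(spec, n_receptors, receptor_spacing_deg, dt_s)
}

#' Render a grating with independent flicker and motion clocks
#'
#' Identical to [make_grating_stimulus()] except that the displacement
#' clock (`motion_hz`) and the contrast-reversal clock (`flicker_hz`) are
#' taken from the spec independently; either may be zero. `flicker_hz = 0`
#' reduces to phi motion, and `flicker_hz = motion_hz` with zero phase
#' offset reduces to reverse-phi, bit-for-bit.
#'
#' @inheritParams make_grating_stimulus
#' @return A [spacetime_stimulus()].
#' @export
make_decoupled_stimulus <- function(spec, n_receptors,
                                    receptor_spacing_deg = 4, dt_s = 0.001) {
  stopifnot(inherits(spec, "stimulus_spec"),
            spec$motion_hz >= 0, spec$flicker_hz >= 0)
  render_grating(spec, n_receptors, receptor_spacing_deg, dt_s)
}

#' Rigidly translating one-dimensional noise
#'
#' Draws a random luminance profile on a master grid oversampled by
#' `upsample` relative to the receptor spacing and translates it rigidly at
#' constant velocity, sampling each receptor by nearest-sample displacement
#' (displacements are quantized to `receptor_spacing_deg / upsample`). The
#' master pattern wraps circularly.
#'
#' @param velocity_deg_s Translation velocity, degrees/s (sign = direction).
#' @param n_receptors Number of receptors (> 0).
#' @param dt_s Time step, seconds.
#' @param seed Integer seed; required for reproducibility.
#' @param duration_s Duration, seconds.
#' @param receptor_spacing_deg Receptor spacing, degrees.
#' @param upsample Master-grid oversampling factor (samples per receptor
#'   spacing).
#' @param luminance_range Range of the uniform luminance draw.
#' @return A [spacetime_stimulus()] whose `direction` is the sign of the
#'   velocity.
#' @export
make_translating_noise <- function(velocity_deg_s, n_receptors, dt_s, seed,
                                   duration_s = 2,
                                   receptor_spacing_deg = 4,
                                   upsample = 10,
                                   luminance_range = c(1.05, 1.55)) {
  stopifnot(n_receptors >= 1, dt_s > 0, !missing(seed), upsample >= 1)
  nt <- round(duration_s / dt_s)
  m <- n_receptors * upsample
  # luminance values are drawn at receptor resolution and held constant
  # across sub-receptor master cells, so the profile is band-limited near
  # the receptor sampling rate while displacements remain sub-receptor
  master <- withr::with_seed(
    seed,
    rep(stats::runif(n_receptors, luminance_range[1], luminance_range[2]),
        each = upsample)
  )
  quantum <- receptor_spacing_deg / upsample
  t <- (seq_len(nt) - 1) * dt_s
  shift <- round(velocity_deg_s * t / quantum)
  # receptor r samples master at index r*upsample - shift (pattern moving
  # toward +x means the profile seen at a fixed receptor moves backward)
  idx0 <- (seq_len(n_receptors) - 1) * upsample
  ind <- outer(-shift, idx0, `+`) %% m + 1
  lum <- matrix(master[ind], nt, n_receptors)
  spacetime_stimulus(lum, receptor_spacing_deg, dt_s,
                     direction = if (velocity_deg_s < 0) -1 else 1)
}

#' Half-wave rectify a stimulus about its mean luminance
#'
#' ON rectification replaces every value below the stimulus-wide mean by the
#' mean; OFF rectification replaces every value above it. Equivalently the
#' demeaned pattern is half-wave rectified and the mean restored, so
#' `ON(s) + OFF(s) - mean(s) = s` pointwise.
#'
#' @param stim A [spacetime_stimulus()].
#' @param polarity `"ON"` or `"OFF"`.
#' @return A rectified [spacetime_stimulus()].
#' @export
rectify_stimulus <- function(stim, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  m <- mean(stim$luminance)
  out <- stim
  out$luminance <- if (polarity == "ON") {
    pmax(stim$luminance, m)
  } else {
    pmin(stim$luminance, m)
  }
  out
}

#' Mirror a stimulus along the receptor axis
#'
#' Reverses the spatial axis of the luminance array and flips the nominal
#' direction. For periodic gratings this is equivalent (up to boundary
#' phase) to reversing the motion direction.
#'
#' @param stim A [spacetime_stimulus()].
#' @return The mirrored [spacetime_stimulus()].
#' @export
mirror_stimulus <- function(stim) {
  out <- stim
  out$luminance <- stim$luminance[, rev(seq_len(ncol(stim$luminance))),
                                  drop = FALSE]
  out$direction <- -stim$direction
  if (!is.null(out$spec)) out$spec$direction <- -out$spec$direction
  out
}
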