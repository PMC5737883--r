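# Centered DFT frequency axis: cycles per unit, zero at index floor(n/2)+1.
centered_freqs <- function(n, d) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * d)
}

fftshift_idx <- function(n) {
  # rotate so the zero-frequency bin lands at index floor(n/2) + 1,
  # matching centered_freqs() for both even and odd n
  h <- n - floor(n / 2) + 1
  c(h:n, seq_len(h - 1))
}

#' Spatiotemporal magnitude spectrum of a stimulus
#'
#' Demeans the luminance array and computes its two-dimensional discrete
#' Fourier magnitude over (temporal frequency, spatial frequency), with a
#' rectangular window (no taper) and both axes centered so that zero
#' frequency sits at the grid center. A rigidly translating pattern
#' concentrates its energy along the line `f_t = -v * f_x` through the
#' origin, whose slope gives the true velocity.
#'
#' @param stim A [spacetime_stimulus()] with at least two time samples and
#'   two receptors.
#' @return An object of class `motion_spectrum`: a list with `magnitude`
#'   (matrix, temporal frequency by spatial frequency), `freq_t_hz`,
#'   `freq_x_cpd` (cycles/degree), and the originating stimulus metadata.
#' @export
magnitude_spectrum <- function(stim) {
  stopifnot(inherits(stim, "spacetime_stimulus"))
  lum <- stim$luminance
  if (nrow(lum) < 2 || ncol(lum) < 2) {
    stop("stimulus must have at least 2 time samples and 2 receptors",
         call. = FALSE)
  }
  x <- lum - mean(lum)
  f <- stats::fft(x)
  mag <- Mod(f)[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
  structure(
    list(
      magnitude = mag,
      freq_t_hz = centered_freqs(nrow(x), stim$dt_s),
      freq_x_cpd = centered_freqs(ncol(x), stim$receptor_spacing_deg),
      dt_s = stim$dt_s,
      receptor_spacing_deg = stim$receptor_spacing_deg,
      direction = stim$direction
    ),
    class = "motion_spectrum"
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.motion_spectrum <- function(x, ...) {
  tibble::tibble(
    freq_x_cpd = rep(x$freq_x_cpd, each = length(x$freq_t_hz)),
    freq_t_hz = rep(x$freq_t_hz, length(x$freq_x_cpd)),
    magnitude = as.vector(x$magnitude)
  )
}

#' @export
print.motion_spectrum <- function(x, ...) {
  cat(sprintf(
    "<motion_spectrum> %d temporal x %d spatial frequency bins\n",
    length(x$freq_t_hz), length(x$freq_x_cpd)
  ))
  invisible(x)
}

# Quadrant membership masks for a centered spectrum. The zero-frequency row
# and column are excluded (they carry static-pattern and full-field flicker
# energy that belongs to neither direction); for even grid sizes the
# Nyquist row/column, whose frequency sign is ambiguous, is excluded too.
quadrant_masks <- function(freq_t, freq_x) {
  st <- sign(freq_t)
  sx <- sign(freq_x)
  if (length(freq_t) %% 2 == 0) st[1] <- 0
  if (length(freq_x) %% 2 == 0) sx[1] <- 0
  s <- outer(st, sx)
  list(same = s > 0, opposite = s < 0)
}

#' Calibrate the quadrant-to-direction convention
#'
#' Renders a reference sinusoid drifting rightward (toward increasing
#' azimuth) on a grid of the given shape, transforms it, and records which
#' quadrant pair -- `same` for `{(+f_x, +f_t), (-f_x, -f_t)}` or `opposite`
#' for `{(+f_x, -f_t), (-f_x, +f_t)}` -- captures its energy. The resulting
#' tag fixes the preferred-direction quadrant assignment used by
#' [quadrant_energy()]. The procedure is deterministic and depends only on
#' the FFT sign convention, not on grid size.
#'
#' @param n_receptors,n_time Grid shape of the reference stimulus.
#' @param dt_s Time step, seconds.
#' @param receptor_spacing_deg Receptor spacing, degrees.
#' @return An object of class `quadrant_convention` with element
#'   `rightward` (`"same"` or `"opposite"`).
#' @export
calibrate_convention <- function(n_receptors = 16, n_time = 64,
                                 dt_s = 0.01, receptor_spacing_deg = 4) {
  t <- (seq_len(n_time) - 1) * dt_s
  x <- (seq_len(n_receptors) - 1) * receptor_spacing_deg
  fx <- 1 / (n_receptors * receptor_spacing_deg)  # one spatial cycle
  ft <- 4 / (n_time * dt_s)                        # four temporal cycles
  # rightward drift: pattern cos(2*pi*(fx*x - ft*t)) moves toward +x
  lum <- outer(-ft * t, fx * x, `+`)
  lum <- cos(2 * pi * lum)
  stim <- spacetime_stimulus(lum, receptor_spacing_deg, dt_s)
  sp <- magnitude_spectrum(stim)
  masks <- quadrant_masks(sp$freq_t_hz, sp$freq_x_cpd)
  e_same <- mean(sp$magnitude[masks$same]^2)
  e_opp <- mean(sp$magnitude[masks$opposite]^2)
  if (isTRUE(all.equal(e_same, e_opp))) {
    stop("ambiguous calibration: equal energy in both quadrant pairs",
         call. = FALSE)
  }
  structure(
    list(rightward = if (e_same > e_opp) "same" else "opposite"),
    class = "quadrant_convention"
  )
}

#' Mean motion energy per direction-signaling quadrant pair
#'
#' Averages squared spectral magnitude (or magnitude, see `measure`) within
#' the two quadrant pairs of the centered spatiotemporal spectrum. The pair
#' signaling the stimulus's nominal direction is reported as `e_pd`, the
#' opposite pair as `e_nd`. Zero-frequency axes and (for even grids)
#' Nyquist bins are excluded from the means.
#'
#' @param stim A [spacetime_stimulus()]; its `direction` field defines
#'   which pair is "preferred".
#' @param convention A [calibrate_convention()] result. The default
#'   calibrates on the fly (the calibration is deterministic); pass `NULL`
#'   explicitly to signal an uncalibrated call, which is an error.
#' @param measure `"energy"` (squared magnitude, the default) or
#'   `"magnitude"`.
#' @return An object of class `quadrant_energy`: list with `e_pd`, `e_nd`,
#'   `convention_tag`, `direction`, `measure`.
#' @export
quadrant_energy <- function(stim, convention = calibrate_convention(),
                            measure = c("energy", "magnitude")) {
  measure <- match.arg(measure)
  if (is.null(convention)) {
    stop("quadrant convention has not been calibrated; run calibrate_convention()",
         call. = FALSE)
  }
  stopifnot(inherits(convention, "quadrant_convention"))
  sp <- magnitude_spectrum(stim)
  masks <- quadrant_masks(sp$freq_t_hz, sp$freq_x_cpd)
  val <- if (measure == "energy") sp$magnitude^2 else sp$magnitude
  e_same <- mean(val[masks$same])
  e_opp <- mean(val[masks$opposite])
  e_right <- if (convention$rightward == "same") e_same else e_opp
  e_left <- if (convention$rightward == "same") e_opp else e_same
  pd_right <- stim$direction >= 0
  structure(
    list(
      e_pd = if (pd_right) e_right else e_left,
      e_nd = if (pd_right) e_left else e_right,
      convention_tag = convention$rightward,
      direction = stim$direction,
      measure = measure
    ),
    class = "quadrant_energy"
  )
}

#' @export
print.quadrant_energy <- function(x, ...) {
  cat(sprintf(
    "<quadrant_energy> e_pd = %.4g, e_nd = %.4g (ratio %.3g, %s)\n",
    x$e_pd, x$e_nd, x$e_pd / x$e_nd, x$measure
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quadrant_energy <- function(x, ...) {
  tibble::tibble(
    e_pd = x$e_pd, e_nd = x$e_nd, ratio = x$e_pd / x$e_nd,
    direction = x$direction, measure = x$measure
  )
}
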