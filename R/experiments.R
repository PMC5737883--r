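#' Logarithmic velocity grid
#'
#' The standard grid for tuning experiments: `n` log-spaced velocities
#' between `from` and `to` degrees/s (default 20 points, 1 to 1000).
#'
#' @param n Number of grid points.
#' @param from,to Velocity range, degrees/s.
#' @return Strictly increasing numeric vector.
#' @export
default_velocity_grid <- function(n = 20, from = 1, to = 1000) {
  10^seq(log10(from), log10(to), length.out = n)
}

# One grating simulation -> mean response, averaged over both initial
# polarity states of the non-gray stripes (emulating per-trial polarity
# randomization and removing polarity-dependent transients).
simulate_condition <- function(cfg, wavelength_deg, polarity_mode,
                               velocity_deg_s = NULL, motion_hz = NULL,
                               flicker_hz = NULL, phase_offset_frac = 0,
                               duration_s = 10, motion_onset_s = 0.5,
                               motion_offset_s = 9.5,
                               average_polarity = TRUE,
                               window = NULL) {
  polarities <- if (average_polarity) c("bright", "dark") else "bright"
  vals <- vapply(polarities, function(pol) {
    spec <- stimulus_spec(
      wavelength_deg = wavelength_deg,
      velocity_deg_s = velocity_deg_s,
      motion_hz = motion_hz,
      step_deg = cfg$receptor_spacing_deg,
      polarity_mode = polarity_mode,
      flicker_hz = flicker_hz,
      phase_offset_frac = phase_offset_frac,
      duration_s = duration_s,
      motion_onset_s = motion_onset_s,
      motion_offset_s = motion_offset_s,
      initial_polarity = pol
    )
    stim <- render_grating(spec, cfg$n_detectors + 1,
                           cfg$receptor_spacing_deg, cfg$dt_s)
    mean_response(simulate_emd(stim, cfg), window = window)
  }, numeric(1))
  mean(vals)
}

new_tuning_curve <- function(df, cfg, condition) {
  class(df) <- c("tuning_curve", class(df))
  attr(df, "config") <- cfg
  attr(df, "condition") <- condition
  attr(df, "normalized") <- FALSE
  df
}

#' Velocity tuning of a detector array
#'
#' Computes the time- and space-averaged array response for a grating at
#' each velocity of a (strictly increasing) grid, with the spatial step
#' fixed at one receptor spacing. Each point averages two simulations, one
#' per initial polarity state.
#'
#' @param cfg A [detector_config()] (its `model` field selects 2Q or 4Q).
#' @param wavelength_deg Grating wavelength, degrees.
#' @param polarity_mode `"phi"` or `"reverse-phi"`.
#' @param velocities Velocity grid, degrees/s.
#' @param phase_offset_frac Flicker/motion phase offset (reverse-phi only);
#'   0.5 gives the out-of-phase control.
#' @param duration_s,motion_onset_s,motion_offset_s Trial structure,
#'   seconds.
#' @param average_polarity Average over bright- and dark-starting stripes?
#' @return A `tuning_curve`: tibble with `velocity_deg_s` and `response`,
#'   carrying the config and condition as attributes.
#' @export
velocity_tuning <- function(cfg,
                            wavelength_deg = 90,
                            polarity_mode = c("phi", "reverse-phi"),
                            velocities = default_velocity_grid(),
                            phase_offset_frac = 0,
                            duration_s = 10,
                            motion_onset_s = 0.5,
                            motion_offset_s = 9.5,
                            average_polarity = TRUE) {
  polarity_mode <- match.arg(polarity_mode)
  stopifnot(all(diff(velocities) > 0))
  responses <- vapply(velocities, function(v) {
    tryCatch(
      simulate_condition(cfg, wavelength_deg, polarity_mode,
                         velocity_deg_s = v,
                         phase_offset_frac = phase_offset_frac,
                         duration_s = duration_s,
                         motion_onset_s = motion_onset_s,
                         motion_offset_s = motion_offset_s,
                         average_polarity = average_polarity),
      error = function(e) {
        stop(sprintf("simulation failed at velocity %g deg/s: %s",
                     v, conditionMessage(e)), call. = FALSE)
      }
    )
  }, numeric(1))
  new_tuning_curve(
    tibble::tibble(velocity_deg_s = velocities, response = responses),
    cfg,
    list(model = cfg$model, wavelength_deg = wavelength_deg,
         polarity_mode = polarity_mode,
         phase_offset_frac = phase_offset_frac,
         dc_frac_on = cfg$dc_frac_on, dc_frac_off = cfg$dc_frac_off)
  )
}

#' Velocity of the response extremum
#'
#' Location of the largest response by the chosen sign convention:
#' `"abs"` (largest magnitude), `"positive"` (largest response), or
#' `"negative"` (most negative response, the trough). Ties break toward
#' the lower velocity.
#'
#' @param curve A [velocity_tuning()] result (or any tibble with
#'   `velocity_deg_s` and `response`).
#' @param sign Extremum convention.
#' @return Velocity in degrees/s.
#' @export
peak_velocity <- function(curve, sign = c("abs", "positive", "negative")) {
  sign <- match.arg(sign)
  v <- curve$velocity_deg_s
  r <- curve$response
  if (all(r == 0)) stop("all-zero tuning curve has no peak", call. = FALSE)
  ord <- order(v)
  v <- v[ord]; r <- r[ord]
  key <- switch(sign, abs = abs(r), positive = r, negative = -r)
  v[which.max(key)]  # which.max takes the first (lowest-velocity) tie
}

#' Scan a filter time constant
#'
#' Recomputes phi and reverse-phi velocity tuning for each value of one
#' filter time constant while the other is held at the configured value.
#'
#' @param cfg A [detector_config()].
#' @param which_filter `"LP"` (delay-arm low-pass) or `"HP"` (input
#'   high-pass).
#' @param taus Time constants to scan, seconds; each must exceed the
#'   integration step.
#' @param wavelength_deg Grating wavelength, degrees.
#' @param velocities Velocity grid, degrees/s.
#' @param polarity_modes Stimulus classes to include.
#' @param ... Passed to [velocity_tuning()].
#' @return A `tau_scan`: long tibble with `tau_s`, `polarity_mode`,
#'   `velocity_deg_s`, `response`.
#' @export
tau_scan <- function(cfg, which_filter = c("LP", "HP"), taus,
                     wavelength_deg = 90,
                     velocities = default_velocity_grid(),
                     polarity_modes = c("phi", "reverse-phi"), ...) {
  which_filter <- match.arg(which_filter)
  if (any(taus <= cfg$dt_s)) {
    stop("every scanned tau must exceed the integration step dt_s",
         call. = FALSE)
  }
  df <- tidyr::expand_grid(tau_s = taus, polarity_mode = polarity_modes)
  res <- purrr::pmap(df, function(tau_s, polarity_mode) {
    cfg_i <- cfg
    if (which_filter == "LP") cfg_i$tau_lp_s <- tau_s else cfg_i$tau_hp_s <- tau_s
    velocity_tuning(cfg_i, wavelength_deg, polarity_mode,
                    velocities = velocities, ...)
  })
  out <- dplyr::bind_cols(
    df[rep(seq_len(nrow(df)), each = length(velocities)), ],
    dplyr::bind_rows(lapply(res, tibble::as_tibble))
  )
  class(out) <- c("tau_scan", class(out))
  attr(out, "which_filter") <- which_filter
  attr(out, "config") <- cfg
  out
}

#' Scan the tonic (DC) input fraction of one subunit
#'
#' Isolates one 2Q subunit (the other pathway's weight is set to zero) and
#' maps its mean reverse-phi response over a grid of DC fractions and
#' velocities. The DC fraction regulates how strictly the pathway is
#' ON/OFF separated, and thereby the balance between illusory (inverted)
#' and veridical output.
#'
#' @param cfg A [detector_config()] (model forced to 2Q).
#' @param subunit `"ON"` or `"OFF"`.
#' @param dc_values DC fractions to scan (may span negative to positive).
#' @param wavelength_deg Grating wavelength, degrees.
#' @param velocities Velocity grid, degrees/s.
#' @param normalize Divide responses by the map's maximum absolute value?
#' @param ... Passed to [velocity_tuning()].
#' @return A `dc_scan`: long tibble with `dc_frac`, `velocity_deg_s`,
#'   `response`.
#' @export
dc_scan <- function(cfg, subunit = c("ON", "OFF"), dc_values,
                    wavelength_deg = 90,
                    velocities = default_velocity_grid(),
                    normalize = FALSE, ...) {
  subunit <- match.arg(subunit)
  curves <- lapply(dc_values, function(dc) {
    cfg_i <- cfg
    cfg_i$model <- "2Q"
    if (subunit == "ON") {
      cfg_i$w_off <- 0; cfg_i$w_on <- 1; cfg_i$dc_frac_on <- dc
    } else {
      cfg_i$w_on <- 0; cfg_i$w_off <- 1; cfg_i$dc_frac_off <- dc
    }
    velocity_tuning(cfg_i, wavelength_deg, "reverse-phi",
                    velocities = velocities, ...)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(dc_frac = rep(dc_values, each = length(velocities))),
    dplyr::bind_rows(lapply(curves, tibble::as_tibble))
  )
  if (normalize) out$response <- out$response / max(abs(out$response))
  class(out) <- c("dc_scan", class(out))
  attr(out, "subunit") <- subunit
  attr(out, "normalized") <- normalize
  attr(out, "config") <- cfg
  out
}

#' Response matrix over decoupled flicker and motion frequencies
#'
#' Mean array response for every combination of contrast-reversal rate
#' (`flicker_hz`) and displacement rate (`motion_hz`), with the step fixed
#' at one receptor spacing so equivalent velocities are
#' `motion_hz * step`. The `flicker_hz = 0` row reproduces phi tuning and
#' the diagonal reproduces reverse-phi tuning exactly (identical stimulus
#' construction).
#'
#' @param cfg A [detector_config()].
#' @param flicker_hz,motion_hz Frequency grids, Hz (default
#'   `{0, 8, 16, 32, 64}`).
#' @param wavelength_deg Grating wavelength, degrees.
#' @param duration_s,motion_onset_s,motion_offset_s Trial structure,
#'   seconds.
#' @return A `response_matrix`: long tibble with `flicker_hz`,
#'   `motion_hz`, `velocity_deg_s`, `response`; the raw (unnormalized)
#'   responses are kept and the matrix maximum is stored in the
#'   `normalization` attribute.
#' @export
flicker_motion_matrix <- function(cfg,
                                  flicker_hz = c(0, 8, 16, 32, 64),
                                  motion_hz = c(0, 8, 16, 32, 64),
                                  wavelength_deg = 90,
                                  duration_s = 10,
                                  motion_onset_s = 0.5,
                                  motion_offset_s = 9.5) {
  grid <- tidyr::expand_grid(flicker_hz = flicker_hz, motion_hz = motion_hz)
  grid$velocity_deg_s <- grid$motion_hz * cfg$receptor_spacing_deg
  grid$response <- purrr::pmap_dbl(
    grid[c("flicker_hz", "motion_hz")],
    function(flicker_hz, motion_hz) {
      mode <- if (flicker_hz == 0) "phi" else "reverse-phi"
      simulate_condition(cfg, wavelength_deg, mode,
                         motion_hz = motion_hz, flicker_hz = flicker_hz,
                         duration_s = duration_s,
                         motion_onset_s = motion_onset_s,
                         motion_offset_s = motion_offset_s)
    }
  )
  class(grid) <- c("response_matrix", class(grid))
  attr(grid, "config") <- cfg
  attr(grid, "wavelength_deg") <- wavelength_deg
  attr(grid, "normalization") <- max(grid$response)
  attr(grid, "normalized") <- FALSE
  grid
}

#' Normalize a tuning curve, scan, or response matrix
#'
#' Divides responses by the largest absolute response (per-panel
#' convention). Pass other result objects through `reference` to normalize
#' a group of curves jointly by their shared extremum, as when several
#' curves share a display panel. `method = "max"` divides by the (signed)
#' maximum instead, the convention used for flicker-by-motion matrices.
#'
#' @param x A `tuning_curve`, `tau_scan`, `dc_scan`, or `response_matrix`.
#' @param reference Optional list of additional objects (or a single
#'   object) included when computing the normalizer.
#' @param method `"max_abs"` or `"max"`.
#' @return `x` with `response` rescaled and the `normalized` attribute set.
#' @export
normalize_curve <- function(x, reference = NULL,
                            method = c("max_abs", "max")) {
  method <- match.arg(method)
  pool <- x$response
  if (!is.null(reference)) {
    if (!is.list(reference) || is.data.frame(reference)) {
      reference <- list(reference)
    }
    pool <- c(pool, unlist(lapply(reference, function(r) r$response)))
  }
  denom <- if (method == "max_abs") max(abs(pool)) else max(pool)
  if (denom == 0) stop("cannot normalize an all-zero response", call. = FALSE)
  x$response <- x$response / denom
  attr(x, "normalized") <- TRUE
  attr(x, "normalization") <- denom
  x
}

#' @exportS3Method generics::tidy
tidy.tuning_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  cond <- attr(x, "condition")
  if (!is.null(cond)) {
    out$model <- cond$model
    out$wavelength_deg <- cond$wavelength_deg
    out$polarity_mode <- cond$polarity_mode
  }
  out
}

#' @exportS3Method generics::glance
glance.tuning_curve <- function(x, ...) {
  tibble::tibble(
    peak_velocity_deg_s = peak_velocity(x, "positive"),
    peak_response = max(x$response),
    trough_velocity_deg_s = peak_velocity(x, "negative"),
    trough_response = min(x$response),
    n_velocities = nrow(x),
    normalized = isTRUE(attr(x, "normalized"))
  )
}

#' Sign structure of a tuning curve at a resolution floor
#'
#' Simulated tuning curves carry small numerical residues (finite-array
#' boundary truncation, pinned pattern phase) of up to a few percent of the
#' curve's peak magnitude, so raw signs of near-zero responses are not
#' meaningful. `response_signs()` classifies each response as -1, 0, or +1,
#' treating values below `floor_frac` of the maximum absolute response as
#' zero; `sign_changes()` counts the sign flips along increasing velocity
#' among the classified (non-zero) responses.
#'
#' @param curve A tuning curve (or any tibble with a `response` column;
#'   `sign_changes()` orders by `velocity_deg_s` when present).
#' @param floor_frac Resolution floor as a fraction of `max(abs(response))`.
#' @return `response_signs()`: integer vector in `{-1, 0, 1}`.
#'   `sign_changes()`: a count.
#' @export
response_signs <- function(curve, floor_frac = 0.05) {
  r <- curve$response
  floor_val <- floor_frac * max(abs(r))
  ifelse(abs(r) <= floor_val, 0L, as.integer(sign(r)))
}

#' @rdname response_signs
#' @export
sign_changes <- function(curve, floor_frac = 0.05) {
  ord <- if ("velocity_deg_s" %in% names(curve)) {
    order(curve$velocity_deg_s)
  } else {
    seq_len(nrow(curve))
  }
  s <- response_signs(curve[ord, , drop = FALSE], floor_frac)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
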