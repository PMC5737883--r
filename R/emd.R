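#' Configure an elementary-motion-detector array
#'
#' Collects every parameter of the correlator models. Both architectures
#' share the front end: each receptor signal is high-pass filtered
#' (`tau_hp_s`) and, where a DC fraction is non-zero, a tonic copy of the
#' raw luminance (`dc_frac * s`) is added back, leaving residual
#' sensitivity to absolute luminance. The four-quadrant (`"4Q"`) model
#' multiplies the resulting arm signals directly (sign-correct
#' multiplication over all ON/OFF combinations); the two-quadrant (`"2Q"`)
#' model first half-wave rectifies into ON and OFF channels, which then
#' form separate mirror-symmetric correlators (modelling the fly T4 and T5
#' pathways) whose outputs are summed with weights `w_on` and `w_off`.
#'
#' Defaults follow the standard parameter set for this detector family:
#' `tau_hp_s = 0.25`, `tau_lp_s = 0.05`, 60 detectors at 4 degree spacing
#' (covering 240 degrees of visual space), 1 ms integration step, a display
#' smoothing constant of 200 ms, and a DC fraction of 10% for the 2Q model
#' and 0 for the 4Q model.
#'
#' @param model `"2Q"` or `"4Q"`.
#' @param tau_hp_s High-pass time constant, seconds.
#' @param tau_lp_s Delay-arm low-pass time constant, seconds.
#' @param dc_frac_on,dc_frac_off Tonic input fraction added to the ON/OFF
#'   subunit arm (dimensionless; may be negative). The 4Q model has a
#'   single arm and requires the two fractions to be equal.
#' @param w_on,w_off Output weights of the ON and OFF subunits (2Q only;
#'   set one to zero to isolate the other pathway).
#' @param n_detectors Number of detectors; the stimulus must provide
#'   `n_detectors + 1` receptor columns.
#' @param receptor_spacing_deg Receptor spacing, degrees.
#' @param dt_s Integration step, seconds; must be smaller than both time
#'   constants.
#' @param display_tau_s Post-hoc smoothing constant for time-resolved
#'   output, seconds.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(model = c("2Q", "4Q"),
                            tau_hp_s = 0.250,
                            tau_lp_s = 0.050,
                            dc_frac_on = NULL,
                            dc_frac_off = NULL,
                            w_on = 1,
                            w_off = 1,
                            n_detectors = 60,
                            receptor_spacing_deg = 4,
                            dt_s = 0.001,
                            display_tau_s = 0.200) {
  model <- match.arg(model)
  default_dc <- if (model == "2Q") 0.10 else 0
  if (is.null(dc_frac_on)) dc_frac_on <- default_dc
  if (is.null(dc_frac_off)) dc_frac_off <- default_dc
  stopifnot(tau_hp_s > 0, tau_lp_s > 0, dt_s > 0,
            n_detectors >= 1, receptor_spacing_deg > 0, display_tau_s > 0)
  if (dt_s >= min(tau_hp_s, tau_lp_s)) {
    stop("dt_s must be smaller than both time constants", call. = FALSE)
  }
  structure(
    list(
      model = model,
      tau_hp_s = tau_hp_s, tau_lp_s = tau_lp_s,
      dc_frac_on = dc_frac_on, dc_frac_off = dc_frac_off,
      w_on = w_on, w_off = w_off,
      n_detectors = n_detectors,
      receptor_spacing_deg = receptor_spacing_deg,
      dt_s = dt_s,
      display_tau_s = display_tau_s
    ),
    class = "detector_config"
  )
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> %s  tau_hp=%g s  tau_lp=%g s  DC=%g/%g  w=%g/%g\n",
    x$model, x$tau_hp_s, x$tau_lp_s, x$dc_frac_on, x$dc_frac_off,
    x$w_on, x$w_off
  ))
  cat(sprintf("  %d detectors, spacing %g deg, dt %g s\n",
              x$n_detectors, x$receptor_spacing_deg, x$dt_s))
  invisible(x)
}

# Mirror-symmetric correlator stage on channel signals ch (time x receptor):
# detector i = LP(ch_i) * ch_{i+1} - ch_i * LP(ch_{i+1}). Positive output
# signals motion toward increasing receptor index (rightward).
correlate_pairs <- function(ch, tau_lp_s, dt_s) {
  d <- lowpass(ch, tau_lp_s, dt_s)
  r <- ncol(ch)
  left <- seq_len(r - 1)
  right <- left + 1
  d[, left, drop = FALSE] * ch[, right, drop = FALSE] -
    ch[, left, drop = FALSE] * d[, right, drop = FALSE]
}

#' Simulate a detector array on a stimulus
#'
#' Runs the configured correlator array over a space-time stimulus. The
#' stimulus must supply `n_detectors + 1` receptor columns at the
#' configured spacing and time step; detector `i` reads receptors `i` and
#' `i + 1` (no periodic wrap-around). All filters start from the first
#' input sample, so a static lead-in produces no onset transient.
#'
#' For the 4Q model the arm signal is `HP(s) + dc * s` and detector output
#' is the antisymmetric product `LP(a_i) a_{i+1} - a_i LP(a_{i+1})`. For
#' the 2Q model the arm is formed per subunit (`dc_frac_on`,
#' `dc_frac_off`), half-wave rectified into non-negative ON and OFF
#' channels, each channel is correlated separately, and the two subunit
#' outputs are combined with weights `w_on`, `w_off` after the
#' mirror subtraction.
#'
#' @param stim A [spacetime_stimulus()].
#' @param cfg A [detector_config()].
#' @param keep_per_detector Keep the detector-by-time output matrix in the
#'   result (memory permitting)?
#' @return An object of class `detector_output`: list with `summed` (time
#'   series of the spatially summed array output), `time_s`, optionally
#'   `per_detector`, plus the config and stimulus spec used.
#' @export
simulate_emd <- function(stim, cfg, keep_per_detector = FALSE) {
  stopifnot(inherits(stim, "spacetime_stimulus"),
            inherits(cfg, "detector_config"))
  lum <- stim$luminance
  if (ncol(lum) != cfg$n_detectors + 1) {
    stop(sprintf("stimulus provides %d receptors; %d detectors need %d",
                 ncol(lum), cfg$n_detectors, cfg$n_detectors + 1),
         call. = FALSE)
  }
  if (abs(stim$dt_s - cfg$dt_s) > 1e-12) {
    stop("stimulus dt_s does not match detector config dt_s", call. = FALSE)
  }

  hp <- highpass(lum, cfg$tau_hp_s, cfg$dt_s)
  per <- if (cfg$model == "4Q") {
    if (abs(cfg$dc_frac_on - cfg$dc_frac_off) > 1e-12) {
      stop("the 4Q model has a single input arm; dc_frac_on and dc_frac_off must be equal",
           call. = FALSE)
    }
    arm <- hp + cfg$dc_frac_on * lum
    correlate_pairs(arm, cfg$tau_lp_s, cfg$dt_s)
  } else {
    on_ch <- half_wave(hp + cfg$dc_frac_on * lum, "ON")
    off_ch <- half_wave(hp + cfg$dc_frac_off * lum, "OFF")
    cfg$w_on * correlate_pairs(on_ch, cfg$tau_lp_s, cfg$dt_s) +
      cfg$w_off * correlate_pairs(off_ch, cfg$tau_lp_s, cfg$dt_s)
  }

  structure(
    list(
      summed = rowSums(per),
      per_detector = if (keep_per_detector) per else NULL,
      time_s = stimulus_times(stim),
      config = cfg,
      stimulus_spec = stim$spec,
      direction = stim$direction
    ),
    class = "detector_output"
  )
}

#' @export
print.detector_output <- function(x, ...) {
  cat(sprintf(
    "<detector_output> %s model, %d detectors, %d samples (dt %g s)\n",
    x$config$model, x$config$n_detectors, length(x$summed), x$config$dt_s
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.detector_output <- function(x, ...) {
  tibble::tibble(time_s = x$time_s, response = x$summed)
}

# Default analysis window: the motion interval of the originating spec,
# else the full simulation.
default_window <- function(out) {
  sp <- out$stimulus_spec
  if (!is.null(sp)) c(sp$motion_onset_s, sp$motion_offset_s)
  else range(out$time_s) + c(0, out$config$dt_s)
}

#' Time-averaged array response
#'
#' Mean of the spatially summed detector output over a time window
#' (half-open, `[from, to)`); the default window is the stimulus's motion
#' interval.
#'
#' @param out A [simulate_emd()] result.
#' @param window Numeric length-2 `c(from, to)` in seconds.
#' @return A scalar, in model units.
#' @export
mean_response <- function(out, window = NULL) {
  stopifnot(inherits(out, "detector_output"))
  if (is.null(window)) window <- default_window(out)
  keep <- out$time_s >= window[1] & out$time_s < window[2]
  if (!any(keep)) stop("empty averaging window", call. = FALSE)
  mean(out$summed[keep])
}

#' Smoothed time-resolved array response
#'
#' Low-pass filters the summed output with the configured display time
#' constant (default 200 ms), approximating the temporal integration of
#' the visuomotor transformation; used to analyse biphasic response
#' dynamics.
#'
#' @param out A [simulate_emd()] result.
#' @return A tibble with `time_s` and `response` columns (class
#'   `detector_trace`).
#' @export
smooth_display <- function(out) {
  stopifnot(inherits(out, "detector_output"))
  tr <- tibble::tibble(
    time_s = out$time_s,
    response = lowpass(out$summed, out$config$display_tau_s, out$config$dt_s)
  )
  class(tr) <- c("detector_trace", class(tr))
  attr(tr, "stimulus_spec") <- out$stimulus_spec
  attr(tr, "config") <- out$config
  tr
}
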