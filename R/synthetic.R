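# First-order rise/decay response kernel on a time grid: zero before onset,
# saturating rise (tau_rise) while the stimulus moves, exponential decay
# (tau_decay) after offset. The slow decay lets a post-motion summary
# window capture a sustained response component.
response_kernel <- function(time_s, onset_s, offset_s,
                            tau_rise = 0.25, tau_decay = 1.0) {
  k <- numeric(length(time_s))
  up <- time_s >= onset_s & time_s < offset_s
  k[up] <- 1 - exp(-(time_s[up] - onset_s) / tau_rise)
  k_end <- 1 - exp(-(offset_s - onset_s) / tau_rise)
  post <- time_s >= offset_s
  k[post] <- k_end * exp(-(time_s[post] - offset_s) / tau_decay)
  k
}

#' Default planted velocity tuning for synthetic cohorts
#'
#' Ten conditions emulating the behavioral design: phi and reverse-phi at
#' five velocities (16, 32, 64, 128, 256 degrees/s). Phi turning rises
#' with velocity; reverse-phi turning is inverted at low velocities and
#' weakly syndirectional at the highest, mimicking the bilobed tuning of a
#' DC-admitting rectified correlator.
#'
#' @return A tibble with `condition` and `amplitude_deg_s` (the planted
#'   steady-state turning amplitude, degrees/s).
#' @export
default_tuning_profile <- function() {
  v <- c(16, 32, 64, 128, 256)
  tibble::tibble(
    condition = c(paste0("phi_v", v), paste0("revphi_v", v)),
    amplitude_deg_s = c(6, 12, 20, 26, 30,   # phi: rising optomotor gain
                        -5, -9, -12, -4, 3)  # reverse-phi: bilobed
  )
}

#' Specify a synthetic behavioral cohort
#'
#' Ground-truth parameters for [gen_behavior()]. Each trial lasts 3.5 s
#' with motion from 1.0 to 2.0 s, sampled at 20 Hz; turning is the planted
#' condition amplitude times a first-order response kernel, plus a
#' constant per-fly turning bias and white noise. Walking speed is drawn
#' per fly and jitters per trial.
#'
#' @param n_flies Number of flies.
#' @param trials_per_fly Trials per fly (>= 40); condition/direction pairs
#'   are cycled to fill them, so every condition appears in both mirrored
#'   directions.
#' @param tuning_profile Tibble of `condition`, `amplitude_deg_s`.
#' @param turning_noise_sd White-noise SD on turning samples, degrees/s.
#' @param bias_mean,bias_sd Per-fly constant turning-bias distribution,
#'   degrees/s.
#' @param speed_mean,speed_sd Per-fly mean walking-speed distribution,
#'   mm/s (within-trial jitter has SD `speed_sd / 2`).
#' @param tau_rise_s,tau_decay_s Response-kernel time constants, seconds.
#' @param trial_duration_s,motion_onset_s,motion_offset_s Trial structure,
#'   seconds.
#' @param rate_hz Behavioral sampling rate, Hz.
#' @param seed Integer seed; required.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_flies = 10,
                        trials_per_fly = 70,
                        tuning_profile = default_tuning_profile(),
                        turning_noise_sd = 15,
                        bias_mean = 0, bias_sd = 1,
                        speed_mean = 10, speed_sd = 2,
                        tau_rise_s = 0.25, tau_decay_s = 1.0,
                        trial_duration_s = 3.5,
                        motion_onset_s = 1.0, motion_offset_s = 2.0,
                        rate_hz = 20,
                        seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(trials_per_fly >= 40, n_flies >= 1,
            turning_noise_sd >= 0, bias_sd >= 0, speed_sd >= 0,
            all(c("condition", "amplitude_deg_s") %in% names(tuning_profile)))
  structure(
    list(n_flies = n_flies, trials_per_fly = trials_per_fly,
         tuning_profile = tuning_profile,
         turning_noise_sd = turning_noise_sd,
         bias_mean = bias_mean, bias_sd = bias_sd,
         speed_mean = speed_mean, speed_sd = speed_sd,
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         trial_duration_s = trial_duration_s,
         motion_onset_s = motion_onset_s, motion_offset_s = motion_offset_s,
         rate_hz = rate_hz, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic behavioral cohort
#'
#' Pure function of its spec (seed included): repeated calls are
#' byte-identical. Conditions and mirrored directions are cycled across
#' the trials of each fly in a per-fly random order.
#'
#' The planted ground truth is stored in the `ground_truth` attribute as a
#' tibble with, per condition, the planted amplitude and
#' `expected_turning_deg_s`: the amplitude scaled by the response kernel's
#' mean over the standard `[1.5, 3.0)` s summary window, i.e. the value an
#' unbiased pipeline ([mirror_subtract()] then [summarize_turning()])
#' recovers exactly in the noiseless case.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `fly`, `trial`, `condition`, `direction`,
#'   `time_s`, `turning_deg_s`, `walking_speed_mm_s`; attributes
#'   `ground_truth` and `spec`.
#' @export
gen_behavior <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nt <- round(spec$trial_duration_s * spec$rate_hz)
  time_s <- (seq_len(nt) - 1) / spec$rate_hz
  kern <- response_kernel(time_s, spec$motion_onset_s, spec$motion_offset_s,
                          spec$tau_rise_s, spec$tau_decay_s)
  win <- time_s >= 1.5 & time_s < 3.0
  kern_gain <- mean(kern[win])

  cells <- tidyr::expand_grid(condition = spec$tuning_profile$condition,
                              direction = c(1, -1))
  amp <- stats::setNames(spec$tuning_profile$amplitude_deg_s,
                         spec$tuning_profile$condition)

  trials <- withr::with_seed(spec$seed, {
    purrr::map(seq_len(spec$n_flies), function(f) {
      bias <- stats::rnorm(1, spec$bias_mean, spec$bias_sd)
      fly_speed <- stats::rnorm(1, spec$speed_mean, spec$speed_sd)
      # block-randomized schedule: each consecutive block presents every
      # condition x direction pair once in shuffled order, so any
      # contiguous window of >= 2 * blocksize - 1 trials contains a
      # complete block (all conditions in both directions)
      reps <- ceiling(spec$trials_per_fly / nrow(cells))
      sched <- dplyr::bind_rows(lapply(seq_len(reps), function(b) {
        cells[sample.int(nrow(cells)), ]
      }))[seq_len(spec$trials_per_fly), ]
      purrr::map(seq_len(spec$trials_per_fly), function(tr) {
        cond <- sched$condition[tr]
        dir <- sched$direction[tr]
        turning <- bias + dir * amp[[cond]] * kern +
          stats::rnorm(nt, 0, spec$turning_noise_sd)
        speed <- pmax(0, fly_speed + stats::rnorm(nt, 0, spec$speed_sd / 2))
        tibble::tibble(
          fly = sprintf("fly%02d", f), trial = tr,
          condition = cond, direction = dir,
          time_s = time_s,
          turning_deg_s = turning,
          walking_speed_mm_s = speed
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })

  attr(trials, "ground_truth") <- dplyr::mutate(
    spec$tuning_profile,
    expected_turning_deg_s = .data$amplitude_deg_s * kern_gain
  )
  attr(trials, "spec") <- spec
  trials
}

#' Retrieve the planted ground truth of a synthetic data set
#'
#' @param x Output of [gen_behavior()], [gen_voltage()], or
#'   [gen_calcium()].
#' @return The `ground_truth` attribute (a tibble).
#' @export
ground_truth <- function(x) {
  attr(x, "ground_truth")
}

#' Specify synthetic physiological traces
#'
#' Ground truth for [gen_voltage()] and [gen_calcium()]. Amplitudes are
#' planted per (condition, direction) pair; voltage amplitudes are in mV
#' around the resting potential, calcium amplitudes are relative response
#' gains on top of the (slowly bleaching) baseline fluorescence.
#'
#' @param kind `"voltage"` or `"calcium"`.
#' @param amplitudes Tibble with `condition`, `direction`, `amplitude`
#'   columns. Defaults emulate tangential-cell phenomenology for voltage
#'   (sustained PD-phi depolarization, weak ND-phi hyperpolarization,
#'   inverted ND response under reverse-phi) and T4-like tuning for
#'   calcium.
#' @param baseline Resting level (mV) or baseline fluorescence (a.u.,
#'   > 0).
#' @param noise_sd Additive white-noise SD.
#' @param tau_rise_s,tau_decay_s Response kinetics, seconds.
#' @param bleach_frac,bleach_tau_s Calcium only: fraction of baseline lost
#'   to bleaching and its time constant (the baseline stays bounded away
#'   from zero).
#' @param rate_hz Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param stimulus_onset_s,stimulus_offset_s Stimulation interval,
#'   seconds.
#' @param seed Integer seed; required.
#' @return An object of class `physio_spec`.
#' @export
physio_spec <- function(kind = c("voltage", "calcium"),
                        amplitudes = NULL,
                        baseline = NULL,
                        noise_sd = NULL,
                        tau_rise_s = NULL,
                        tau_decay_s = 0.5,
                        bleach_frac = 0.2,
                        bleach_tau_s = 60,
                        rate_hz = NULL,
                        duration_s = NULL,
                        stimulus_onset_s = NULL,
                        stimulus_offset_s = NULL,
                        seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(amplitudes)) {
    amplitudes <- if (kind == "voltage") {
      tibble::tibble(
        condition = c("phi", "phi", "reverse-phi", "reverse-phi"),
        direction = c("PD", "ND", "PD", "ND"),
        amplitude = c(10, -3, 0, 4)
      )
    } else {
      v <- c(16, 32, 64, 128, 256)
      tibble::tibble(
        condition = rep(c(paste0("phi_v", v), paste0("revphi_v", v)), each = 2),
        direction = rep(c("PD", "ND"), 10),
        amplitude = c(
          rbind(c(0.6, 0.9, 1.0, 0.8, 0.5), c(0.05, 0.05, 0.05, 0.05, 0.05)),
          rbind(c(0.05, 0.08, 0.15, 0.45, 0.5), c(0.40, 0.45, 0.30, 0.15, 0.1))
        )
      )
    }
  }
  defaults <- if (kind == "voltage") {
    list(baseline = -50, noise_sd = 0.5, tau_rise_s = 0.05,
         rate_hz = 2000, duration_s = 5, onset = 1, offset = 3)
  } else {
    list(baseline = 100, noise_sd = 0.02, tau_rise_s = 0.3,
         rate_hz = 7.51, duration_s = 30, onset = 10, offset = 14)
  }
  if (is.null(baseline)) baseline <- defaults$baseline
  if (is.null(noise_sd)) noise_sd <- defaults$noise_sd
  if (is.null(tau_rise_s)) tau_rise_s <- defaults$tau_rise_s
  if (is.null(rate_hz)) rate_hz <- defaults$rate_hz
  if (is.null(duration_s)) duration_s <- defaults$duration_s
  if (is.null(stimulus_onset_s)) stimulus_onset_s <- defaults$onset
  if (is.null(stimulus_offset_s)) stimulus_offset_s <- defaults$offset
  stopifnot(noise_sd >= 0, rate_hz > 0,
            stimulus_onset_s < stimulus_offset_s,
            stimulus_offset_s <= duration_s,
            all(c("condition", "direction", "amplitude") %in% names(amplitudes)))
  if (kind == "calcium") {
    stopifnot(baseline > 0, bleach_frac >= 0, bleach_frac < 1)
  }
  structure(
    list(kind = kind, amplitudes = amplitudes, baseline = baseline,
         noise_sd = noise_sd, tau_rise_s = tau_rise_s,
         tau_decay_s = tau_decay_s, bleach_frac = bleach_frac,
         bleach_tau_s = bleach_tau_s, rate_hz = rate_hz,
         duration_s = duration_s, stimulus_onset_s = stimulus_onset_s,
         stimulus_offset_s = stimulus_offset_s, seed = seed),
    class = "physio_spec"
  )
}

gen_physio <- function(spec) {
  nt <- round(spec$duration_s * spec$rate_hz)
  time_s <- (seq_len(nt) - 1) / spec$rate_hz
  kern <- response_kernel(time_s, spec$stimulus_onset_s,
                          spec$stimulus_offset_s,
                          spec$tau_rise_s, spec$tau_decay_s)
  traces <- withr::with_seed(spec$seed, {
    purrr::pmap(spec$amplitudes, function(condition, direction, amplitude) {
      noise <- stats::rnorm(nt, 0, spec$noise_sd)
      if (spec$kind == "voltage") {
        v <- spec$baseline + amplitude * kern + noise
        physio_trace(v, spec$rate_hz, spec$stimulus_onset_s,
                     kind = "membrane_mV",
                     condition = condition, direction = direction)
      } else {
        bleach <- spec$baseline *
          (1 - spec$bleach_frac * (1 - exp(-time_s / spec$bleach_tau_s)))
        f <- bleach * (1 + amplitude * kern) + noise
        physio_trace(f, spec$rate_hz, spec$stimulus_onset_s,
                     kind = "fluorescence_au",
                     condition = condition, direction = direction)
      }
    })
  })
  names(traces) <- paste(spec$amplitudes$condition,
                         spec$amplitudes$direction, sep = "_")
  attr(traces, "ground_truth") <- spec$amplitudes
  attr(traces, "spec") <- spec
  traces
}

#' Generate synthetic membrane-potential traces
#'
#' One trace per planted (condition, direction) pair: resting potential
#' plus amplitude times a first-order response kernel plus white noise,
#' sampled at 2 kHz by default.
#'
#' @param spec A [physio_spec()] with `kind = "voltage"`.
#' @return A named list of [physio_trace()] objects with a `ground_truth`
#'   attribute.
#' @export
gen_voltage <- function(spec) {
  stopifnot(inherits(spec, "physio_spec"), spec$kind == "voltage")
  gen_physio(spec)
}

#' Generate synthetic calcium-fluorescence traces
#'
#' One trace per planted (condition, direction) pair: a strictly positive
#' baseline with slow bounded exponential bleaching, multiplied by
#' `1 + amplitude * kernel`, plus additive white noise, sampled at the
#' indicator frame rate (7.51 Hz by default).
#'
#' @param spec A [physio_spec()] with `kind = "calcium"`.
#' @return A named list of [physio_trace()] objects with a `ground_truth`
#'   attribute.
#' @export
gen_calcium <- function(spec) {
  stopifnot(inherits(spec, "physio_spec"), spec$kind == "calcium")
  gen_physio(spec)
}
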