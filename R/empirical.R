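#' Mirror subtraction of turning traces
#'
#' Every stimulus condition is presented in mirrored versions (pattern
#' moving rightward, `direction = +1`, and leftward, `direction = -1`).
#' Averaging the rightward trials minus the leftward trials, halved,
#' removes any direction-independent additive turning bias exactly while
#' recovering the direction-dependent response.
#'
#' @param trials Tidy trial data: a data frame with at least `condition`,
#'   `direction` (+1/-1), `time_s`, and `turning_deg_s` columns. A `fly`
#'   column, when present, is kept as an additional grouping variable so
#'   the subtraction is performed per fly.
#' @return A tibble with one mean turning trace per (fly,) condition:
#'   columns `condition`, `time_s`, `turning_deg_s` (plus `fly`).
#' @export
mirror_subtract <- function(trials) {
  stopifnot(all(c("condition", "direction", "time_s", "turning_deg_s")
                %in% names(trials)))
  groups <- intersect(c("fly", "condition"), names(trials))
  have <- dplyr::distinct(trials, dplyr::across(dplyr::all_of(c(groups, "direction"))))
  counts <- dplyr::count(have, dplyr::across(dplyr::all_of(groups)))
  bad <- counts[counts$n < 2, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop("both directions required; missing one for: ",
         paste(apply(bad[groups], 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "direction", "time_s")))) |>
    dplyr::summarise(turning_deg_s = mean(.data$turning_deg_s),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "direction",
                       values_from = "turning_deg_s",
                       names_prefix = "dir") |>
    dplyr::mutate(turning_deg_s = (.data$`dir1` - .data$`dir-1`) / 2) |>
    dplyr::select(dplyr::all_of(c(groups, "time_s", "turning_deg_s")))
}

#' Summarize turning over the response window
#'
#' Time-mean of the turning velocity over a window measured from trial
#' onset (half-open, `[from, to)`); the default `[1.5, 3.0)` s captures
#' the sustained response to motion presented from 1.0 to 2.0 s.
#'
#' @param traces A data frame with `time_s` and `turning_deg_s`; any other
#'   columns (e.g. `fly`, `condition`) act as grouping variables.
#' @param window Numeric `c(from, to)`, seconds from trial onset.
#' @return A tibble with one `turning_deg_s` summary per group (or a
#'   single-row tibble when there are no grouping columns).
#' @export
summarize_turning <- function(traces, window = c(1.5, 3.0)) {
  stopifnot(all(c("time_s", "turning_deg_s") %in% names(traces)))
  if (window[1] < min(traces$time_s) - 1e-9 ||
      window[2] > max(traces$time_s) + 1e-9 + min(diff(sort(unique(traces$time_s))))) {
    stop("summary window lies outside the trial", call. = FALSE)
  }
  groups <- setdiff(names(traces),
                    c("time_s", "turning_deg_s", "walking_speed_mm_s",
                      "trial", "direction"))
  traces |>
    dplyr::filter(.data$time_s >= window[1], .data$time_s < window[2]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(turning_deg_s = mean(.data$turning_deg_s),
                     .groups = "drop")
}

#' Post-hoc fly inclusion and trial-window selection
#'
#' For each fly, searches for the earliest contiguous window of
#' `window_trials` trials over which (i) mean walking speed exceeds
#' `speed_threshold` and (ii) the general turning tendency is stable and
#' close to zero, operationalized as the absolute mean turning staying
#' below `bias_tol`. Flies without a qualifying window are excluded.
#'
#' @param trials Tidy trial data with `fly`, `trial`, `time_s`,
#'   `turning_deg_s`, and `walking_speed_mm_s` columns.
#' @param speed_threshold Minimum mean walking speed, mm/s (strict).
#' @param window_trials Number of contiguous trials required.
#' @param bias_tol Maximum absolute mean turning, degrees/s. Defaults to
#'   10% of the cohort's response scale, taken as the maximum absolute
#'   per-trial mean turning across all flies (an observable proxy for the
#'   peak evoked turning response).
#' @return A tibble with one row per retained fly: `fly`, `window_start`,
#'   `window_end` (trial indices, inclusive), `mean_speed_mm_s`,
#'   `mean_turning_deg_s`. The `bias_tol` used is stored as an attribute.
#' @export
select_flies <- function(trials, speed_threshold = 4, window_trials = 40,
                         bias_tol = NULL) {
  stopifnot(all(c("fly", "trial", "turning_deg_s", "walking_speed_mm_s")
                %in% names(trials)))
  per_trial <- trials |>
    dplyr::group_by(.data$fly, .data$trial) |>
    dplyr::summarise(speed = mean(.data$walking_speed_mm_s),
                     turning = mean(.data$turning_deg_s),
                     .groups = "drop") |>
    dplyr::arrange(.data$fly, .data$trial)
  if (is.null(bias_tol)) bias_tol <- 0.1 * max(abs(per_trial$turning))
  res <- per_trial |>
    dplyr::group_by(.data$fly) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      if (n < window_trials) return(NULL)
      for (s in seq_len(n - window_trials + 1)) {
        idx <- s:(s + window_trials - 1)
        ms <- mean(df$speed[idx])
        mt <- mean(df$turning[idx])
        if (ms > speed_threshold && abs(mt) < bias_tol) {
          return(tibble::tibble(
            fly = key$fly,
            window_start = df$trial[idx[1]],
            window_end = df$trial[idx[window_trials]],
            mean_speed_mm_s = ms,
            mean_turning_deg_s = mt
          ))
        }
      }
      NULL
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    res <- tibble::tibble(fly = character(), window_start = integer(),
                          window_end = integer(), mean_speed_mm_s = numeric(),
                          mean_turning_deg_s = numeric())
  }
  attr(res, "bias_tol") <- bias_tol
  attr(res, "speed_threshold") <- speed_threshold
  res
}

#' Construct a physiological trace
#'
#' A regularly sampled single-channel recording (membrane potential or
#' calcium fluorescence) with its sampling rate and stimulus onset.
#'
#' @param samples Numeric vector of samples.
#' @param rate_hz Sampling rate, Hz (2000 for voltage, 7.51 for the
#'   calcium indicator used here).
#' @param stimulus_onset_s Stimulus onset, seconds from record start; must
#'   fall inside the record.
#' @param kind `"membrane_mV"` or `"fluorescence_au"`.
#' @param condition,direction Optional labels (e.g. "phi"/"reverse-phi",
#'   "PD"/"ND").
#' @return A tibble of class `physio_trace` with `time_s` and `value`
#'   columns; metadata stored as attributes.
#' @export
physio_trace <- function(samples, rate_hz, stimulus_onset_s,
                         kind = c("membrane_mV", "fluorescence_au", "dff"),
                         condition = NA_character_,
                         direction = NA_character_) {
  kind <- match.arg(kind)
  stopifnot(rate_hz > 0, stimulus_onset_s >= 0,
            stimulus_onset_s < length(samples) / rate_hz)
  tr <- tibble::tibble(
    time_s = (seq_along(samples) - 1) / rate_hz,
    value = as.numeric(samples)
  )
  class(tr) <- c("physio_trace", class(tr))
  attr(tr, "rate_hz") <- rate_hz
  attr(tr, "stimulus_onset_s") <- stimulus_onset_s
  attr(tr, "kind") <- kind
  attr(tr, "condition") <- condition
  attr(tr, "direction") <- direction
  tr
}

#' Mean depolarization of a voltage trace
#'
#' Baseline-subtracted mean membrane potential over the first
#' `window_s` seconds of stimulation. The baseline is the mean over the
#' `baseline_s` seconds preceding stimulus onset.
#'
#' @param trace A [physio_trace()] of kind `"membrane_mV"`.
#' @param window_s Averaging window length from stimulus onset, seconds.
#' @param baseline_s Pre-onset baseline length, seconds.
#' @return Mean depolarization in mV (scalar).
#' @seealso [cell_included()] for the recording-quality criterion.
#' @export
summarize_voltage <- function(trace, window_s = 2, baseline_s = 0.5) {
  stopifnot(inherits(trace, "physio_trace"))
  if (attr(trace, "kind") != "membrane_mV") {
    stop("summarize_voltage expects a membrane-potential trace", call. = FALSE)
  }
  onset <- attr(trace, "stimulus_onset_s")
  if (onset + window_s > max(trace$time_s) + 1e-9) {
    stop("summary window exceeds the record", call. = FALSE)
  }
  base <- trace$value[trace$time_s >= onset - baseline_s & trace$time_s < onset]
  if (length(base) == 0) stop("no baseline samples before onset", call. = FALSE)
  resp <- trace$value[trace$time_s >= onset & trace$time_s < onset + window_s]
  mean(resp) - mean(base)
}

#' Recording-quality inclusion rule for tangential cells
#'
#' A cell is retained when its mean depolarization for the
#' preferred-direction phi condition reaches `threshold_mv`; cells below
#' the threshold are discarded.
#'
#' @param pd_phi_mv Preferred-direction phi summary (mV), from
#'   [summarize_voltage()].
#' @param threshold_mv Inclusion threshold, mV.
#' @return Logical.
#' @export
cell_included <- function(pd_phi_mv, threshold_mv = 6) {
  pd_phi_mv >= threshold_mv
}

#' Relative fluorescence change with sliding-minimum baseline
#'
#' Estimates the baseline `B(t)` as the minimum of the fluorescence signal
#' within a centered sliding window (default 15 s, truncated at the record
#' edges) and returns `(F - B) / B`. The result is invariant to
#' multiplicative rescaling of the trace.
#'
#' @param trace A [physio_trace()] of kind `"fluorescence_au"` with
#'   strictly positive values.
#' @param window_s Sliding-window length, seconds; must span at least one
#'   sample at the trace's rate.
#' @return The trace with `value` replaced by the ΔF/F series (and the
#'   baseline kept in a `baseline` column).
#' @export
delta_f_over_f <- function(trace, window_s = 15) {
  stopifnot(inherits(trace, "physio_trace"))
  rate <- attr(trace, "rate_hz")
  w <- max(1L, round(window_s * rate))
  if (w < 1) stop("window shorter than one sample", call. = FALSE)
  baseline <- zoo::rollapply(trace$value, width = w, FUN = min,
                             partial = TRUE, align = "center")
  if (any(baseline <= 0)) {
    stop("nonpositive baseline fluorescence; ΔF/F undefined", call. = FALSE)
  }
  out <- trace
  out$baseline <- baseline
  out$value <- (trace$value - baseline) / baseline
  attr(out, "kind") <- "dff"
  out
}

#' Preferred-minus-null imaging summary
#'
#' Difference of the window means of the preferred-direction and
#' null-direction ΔF/F traces, time-averaged over `window` seconds after
#' stimulation onset. Both traces must share the same timebase and onset.
#'
#' @param pd,nd ΔF/F traces ([delta_f_over_f()] output) for preferred and
#'   null direction.
#' @param window Numeric `c(from, to)`, seconds after stimulation onset.
#' @return Scalar PD - ND difference.
#' @export
summarize_imaging <- function(pd, nd, window = c(1, 4)) {
  stopifnot(inherits(pd, "physio_trace"), inherits(nd, "physio_trace"))
  if (nrow(pd) != nrow(nd) ||
      abs(attr(pd, "rate_hz") - attr(nd, "rate_hz")) > 1e-9 ||
      abs(attr(pd, "stimulus_onset_s") - attr(nd, "stimulus_onset_s")) > 1e-9) {
    stop("PD and ND traces must share the same timebase", call. = FALSE)
  }
  onset <- attr(pd, "stimulus_onset_s")
  keep <- pd$time_s >= onset + window[1] & pd$time_s < onset + window[2]
  if (!any(keep)) stop("empty summary window", call. = FALSE)
  mean(pd$value[keep]) - mean(nd$value[keep])
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the input with replacement `n_resamples` times and returns
#' the percentile interval of the resampled means. Deterministic for a
#' given seed.
#'
#' @param x Numeric samples (at least 2).
#' @param n_resamples Number of resamplings.
#' @param level Confidence level.
#' @param seed Integer seed; required.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(x, n_resamples = 1000, level = 0.95, seed) {
  if (length(x) < 1) stop("empty input", call. = FALSE)
  if (length(x) < 2) stop("at least 2 samples required", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  means <- withr::with_seed(seed, {
    m <- matrix(sample(x, n_resamples * length(x), replace = TRUE),
                nrow = n_resamples)
    rowMeans(m)
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(low = ci[1], high = ci[2])
}

#' Downsample a trace by block averaging
#'
#' Integer decimation: consecutive non-overlapping blocks of
#' `rate_hz / target_hz` samples are averaged. The target rate must divide
#' the source rate.
#'
#' @param x A numeric vector or a [physio_trace()].
#' @param target_hz Target sampling rate, Hz.
#' @param rate_hz Source rate, Hz (taken from the trace when `x` is a
#'   `physio_trace`).
#' @return Downsampled vector, or a `physio_trace` at the new rate.
#' @export
downsample <- function(x, target_hz, rate_hz = NULL) {
  if (inherits(x, "physio_trace")) {
    rate <- attr(x, "rate_hz")
    v <- downsample(x$value, target_hz, rate)
    return(physio_trace(v, target_hz, attr(x, "stimulus_onset_s"),
                        kind = attr(x, "kind"),
                        condition = attr(x, "condition"),
                        direction = attr(x, "direction")))
  }
  stopifnot(!is.null(rate_hz))
  factor <- rate_hz / target_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("target_hz must divide rate_hz (integer decimation)", call. = FALSE)
  }
  factor <- round(factor)
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
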