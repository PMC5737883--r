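#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: a space-time raster for
#' stimuli, a line plot on a logarithmic velocity axis for tuning curves
#' (one line per time constant for tau scans), tile maps for
#' flicker-by-motion matrices and DC scans, and a time course for smoothed
#' detector traces.
#'
#' @param object The object to plot.
#' @param ... Ignored.
#' @return A `ggplot`.
#' @name revphi-autoplot
NULL

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.spacetime_stimulus <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$position_deg,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "time (s)", y = "azimuth (deg)", fill = "luminance")
}

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tuning_curve <- function(object, ...) {
  cond <- attr(object, "condition")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$velocity_deg_s,
                                       y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "pattern velocity (deg/s)",
      y = if (isTRUE(attr(object, "normalized"))) "response (norm.)"
          else "response (model units)",
      title = if (!is.null(cond)) {
        sprintf("%s, %s, lambda = %g deg", cond$model, cond$polarity_mode,
                cond$wavelength_deg)
      } else NULL
    )
}

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tau_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$velocity_deg_s,
                                       y = .data$response,
                                       colour = factor(.data$tau_s))) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~polarity_mode, scales = "free_y") +
    ggplot2::labs(x = "pattern velocity (deg/s)", y = "response",
                  colour = sprintf("tau_%s (s)",
                                   tolower(attr(object, "which_filter"))))
}

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.dc_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$velocity_deg_s,
                                       y = .data$dc_frac,
                                       fill = .data$response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "pattern velocity (deg/s)", y = "DC fraction",
                  fill = "response",
                  title = sprintf("%s subunit", attr(object, "subunit")))
}

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.response_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$motion_hz),
                                       y = factor(.data$flicker_hz),
                                       fill = .data$response)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "motion update (Hz)", y = "contrast reversal (Hz)",
                  fill = "response")
}

#' @rdname revphi-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.detector_trace <- function(object, ...) {
  sp <- attr(object, "stimulus_spec")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "smoothed response")
  if (!is.null(sp)) {
    p <- p + ggplot2::annotate("rect", xmin = sp$motion_onset_s,
                               xmax = sp$motion_offset_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  p
}
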