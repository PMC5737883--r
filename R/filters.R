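#' First-order RC low-pass filter (Euler forward)
#'
#' Integrates `y[n+1] = y[n] + (dt/tau) * (x[n] - y[n])` with the initial
#' state set to the first input sample, so a constant input passes through
#' unchanged and a static lead-in produces no transient. Matrices are
#' filtered column-wise (columns = receptors, rows = time).
#'
#' @param x Numeric vector or matrix (time along rows).
#' @param tau_s Time constant, seconds (> 0).
#' @param dt_s Time step, seconds; must satisfy `dt_s < tau_s` (the Euler
#'   step is unstable otherwise).
#' @return Filtered signal with the shape of `x`.
#' @export
lowpass <- function(x, tau_s, dt_s) {
  stopifnot(tau_s > 0, dt_s > 0)
  if (dt_s >= tau_s) {
    stop("dt_s must be smaller than tau_s (unstable Euler step)",
         call. = FALSE)
  }
  a <- dt_s / tau_s
  if (is.matrix(x)) {
    out <- vapply(seq_len(ncol(x)), function(j) lowpass1(x[, j], a),
                  numeric(nrow(x)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    lowpass1(x, a)
  }
}

lowpass1 <- function(x, a) {
  n <- length(x)
  if (n <= 1) return(x)
  rest <- stats::filter(a * x[-n], filter = 1 - a, method = "recursive",
                        init = x[1])
  c(x[1], as.numeric(rest))
}

#' First-order high-pass filter (complement form)
#'
#' Realized as the input minus its own low-pass: `HP(x) = x - LP(x, tau)`,
#' so `HP(x) + LP(x)` reconstructs the input exactly and a constant input
#' maps to zero.
#'
#' @inheritParams lowpass
#' @return Filtered signal with the shape of `x`.
#' @export
highpass <- function(x, tau_s, dt_s) {
  x - lowpass(x, tau_s, dt_s)
}

#' Half-wave rectification into ON and OFF signals
#'
#' `ON` keeps the positive part, `OFF` the sign-flipped negative part, both
#' non-negative: `ON(x) = max(x, 0)`, `OFF(x) = max(-x, 0)`, so
#' `ON(x) - OFF(x) = x`. Rectification is at exactly zero with no offset;
#' zero maps to zero.
#'
#' @param x Numeric vector or matrix.
#' @param polarity `"ON"` or `"OFF"`.
#' @return Non-negative signal with the shape of `x`.
#' @export
half_wave <- function(x, polarity = c("ON", "OFF")) {
  polarity <- match.arg(polarity)
  if (polarity == "ON") pmax(x, 0) else pmax(-x, 0)
}

#' Discrete-time frequency response of the Euler-forward RC filters
#'
#' Complex gain of [lowpass()] (and, via `1 - H`, of [highpass()]) at a
#' given frequency, evaluated from the update recursion rather than the
#' continuous-time transfer function, so it is exact for the discrete
#' filters implemented here.
#'
#' @param freq_hz Frequency, Hz (vectorized).
#' @inheritParams lowpass
#' @return Complex gain(s).
#' @export
lowpass_gain <- function(freq_hz, tau_s, dt_s) {
  a <- dt_s / tau_s
  z <- exp(2i * pi * freq_hz * dt_s)
  a / z / (1 - (1 - a) / z)
}

#' @rdname lowpass_gain
#' @export
highpass_gain <- function(freq_hz, tau_s, dt_s) {
  1 - lowpass_gain(freq_hz, tau_s, dt_s)
}
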