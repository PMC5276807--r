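#' Quantal IPSC waveform
#'
#' Parametric description of the elementary postsynaptic current evoked by a
#' single vesicle.  The functional form is the normalized product of an
#' exponential rise and an exponential decay,
#' \deqn{q(t) = A \, c \,(1 - e^{-t/\tau_r})\, e^{-t/\tau_d},}
#' rescaled (by \eqn{c}) so that the peak equals `amplitude`.  The same
#' object serves as the simulation kernel and as the deconvolution kernel;
#' measured average quantal currents can be used instead wherever a sampled
#' kernel is accepted.
#'
#' @param amplitude Peak current in pA (positive magnitude; the sign of the
#'   rendered current is set by `polarity`).
#' @param tau_rise Rise time constant in ms; must satisfy
#'   `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant in ms.
#' @param polarity `"inward"` (negative current, the usual IPSC at a
#'   chloride-loaded cell held at -70 mV) or `"outward"`.
#' @return An object of class `quantal_waveform`.
#' @examples
#' q <- quantal_waveform(amplitude = 100, tau_rise = 0.3, tau_decay = 5)
#' k <- make_quantal_waveform(q, dt = 0.02, duration = 50)
#' max(abs(k)) # 100
#' @export
quantal_waveform <- function(amplitude, tau_rise, tau_decay,
                             polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop_invalid("amplitude must be positive, got %g", amplitude)
  if (!is.finite(tau_rise) || tau_rise <= 0)
    stop_invalid("tau_rise must be positive, got %g", tau_rise)
  if (!is.finite(tau_decay) || tau_rise >= tau_decay)
    stop_invalid("need 0 < tau_rise < tau_decay (got %g, %g)",
                 tau_rise, tau_decay)
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, polarity = polarity),
            class = "quantal_waveform")
}

#' @export
print.quantal_waveform <- function(x, ...) {
  cat(sprintf(
    "<quantal_waveform> %.3g pA %s, tau_rise %.3g ms, tau_decay %.3g ms (peak at %.3g ms)\n",
    x$amplitude, x$polarity, x$tau_rise, x$tau_decay, waveform_peak_time(x)))
  invisible(x)
}

#' Analytical peak time of the quantal waveform
#'
#' Stationary point of \eqn{(1-e^{-t/\tau_r}) e^{-t/\tau_d}}:
#' \eqn{t^* = \tau_r \ln(1 + \tau_d/\tau_r)}.
#'
#' @param q A [quantal_waveform()].
#' @return Peak time in ms.
#' @export
waveform_peak_time <- function(q) {
  q$tau_rise * log(1 + q$tau_decay / q$tau_rise)
}

#' Sample a quantal waveform on a regular grid
#'
#' @param q A [quantal_waveform()] (or a numeric vector, returned as-is so
#'   measured kernels pass through transparently).
#' @param dt Sampling interval in ms.
#' @param duration Trace duration in ms; at least `10 * tau_decay` is
#'   recommended so the kernel has returned to baseline.
#' @param signed Apply the polarity sign (default `TRUE`).  With
#'   `signed = FALSE` the kernel is positive regardless of polarity, which
#'   is convenient for detection templates.
#' @return Numeric vector of length `round(duration/dt)`; the first sample
#'   (t = 0) is 0 and the maximum absolute value equals the amplitude to
#'   within 0.1%.
#' @export
make_quantal_waveform <- function(q, dt, duration, signed = TRUE) {
  if (is.numeric(q)) return(q)
  stopifnot(inherits(q, "quantal_waveform"))
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive")
  if (!is.finite(duration) || duration <= 0)
    stop_invalid("duration must be positive")
  n <- round(duration / dt)
  t <- (seq_len(n) - 1L) * dt
  tpk <- waveform_peak_time(q)
  norm <- (1 - exp(-tpk / q$tau_rise)) * exp(-tpk / q$tau_decay)
  k <- q$amplitude / norm * (1 - exp(-t / q$tau_rise)) * exp(-t / q$tau_decay)
  if (signed && q$polarity == "inward") k <- -k
  k
}
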