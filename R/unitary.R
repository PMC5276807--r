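# Per-connection unitary IPSC statistics, train amplitudes, alignment,
# decay fitting and feedforward-inhibition measures.

# Response/failure decision: the raw peak of a noise-only window exceeds
# 3 baseline SDs almost surely (max statistics over ~10^3 samples), so the
# decision is taken on a 2 kHz low-pass-smoothed copy of the segment, whose
# noise maximum stays near 1 baseline SD while a genuine response is barely
# attenuated.  Amplitude and latency are still measured on the raw trace.
response_detected <- function(seg, dt, k, base_sd) {
  if (base_sd == 0) return(max(seg) > 0)
  max(gaussian_lowpass(seg, dt, 2)) > k * base_sd
}

# Direction of synaptic deflections: sign of the extremum of the averaged,
# baseline-subtracted post-AP segment.
detect_direction <- function(sweeps) {
  avg <- rowMeans(sweeps$sweeps)
  ap1 <- sweeps$ap_times[[1L]][1L]
  i0 <- max(1L, round(ap1 / sweeps$dt) + 1L)
  seg <- avg[i0:length(avg)] - mean(avg[seq_len(max(i0 - 1L, 1L))])
  if (abs(min(seg)) >= abs(max(seg))) -1 else 1
}

#' Unitary IPSC statistics over a set of trials
#'
#' For each trial (sweep), the baseline is the mean over a window before the
#' (first) AP and the response peak is the extremum within `window` ms after
#' the AP peak.  A trial is a failure when its peak is below
#' `failure_k` baseline standard deviations.  Amplitude statistics (mean,
#' CV = SD/mean, bias-uncorrected skewness) are computed over all trials
#' with failures counted as 0 pA.  Latency is measured per non-failure
#' trial from the AP peak to the IPSC onset, the (interpolated) crossing of
#' 5% of the trial peak.
#'
#' @param sweeps A [sweep_set()] with at least 2 sweeps and one AP time per
#'   sweep.
#' @param window Response search window after the AP peak (ms).
#' @param failure_k Failure threshold in baseline SDs (default 3).
#' @param baseline_window Baseline window (ms) ending 0.5 ms before the AP.
#' @param direction `"auto"` (default), `"negative"` or `"positive"`.
#' @return An object of class `unitary_stats`: `mean_amplitude` (pA, failures
#'   as 0), `failure_fraction`, `cv`, `skewness`, `latency_mean`,
#'   `latency_sd` (ms, non-failure trials; `NA` with `latency_defined =
#'   FALSE` when all trials fail), `decay_tau` (ms, from the average of
#'   non-failure trials), `amplitudes` and `latencies` per trial.
#' @export
measure_unitary <- function(sweeps, window = 20, failure_k = 3,
                            baseline_window = 2,
                            direction = c("auto", "negative", "positive")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  direction <- match.arg(direction)
  if (ncol(sweeps$sweeps) < 2L) stop_invalid("need >= 2 sweeps")
  dt <- sweeps$dt
  sgn <- switch(direction, auto = detect_direction(sweeps),
                negative = -1, positive = 1)
  n_tr <- ncol(sweeps$sweeps)
  amp <- numeric(n_tr)
  lat <- rep(NA_real_, n_tr)
  fail <- logical(n_tr)
  for (s in seq_len(n_tr)) {
    ap <- sweeps$ap_times[[s]][1L]
    y <- sgn * sweeps$sweeps[, s]
    i_ap <- round(ap / dt) + 1L
    b1 <- max(1L, i_ap - round((baseline_window + 0.5) / dt))
    b2 <- max(1L, i_ap - round(0.5 / dt))
    base <- mean(y[b1:b2])
    base_sd <- stats::sd(y[b1:b2])
    i_end <- min(length(y), i_ap + round(window / dt))
    seg <- y[i_ap:i_end] - base
    ipk <- which.max(seg)
    pk <- refine_peak(seg, ipk, 0, dt)
    if (!response_detected(seg, dt, failure_k, base_sd)) {
      fail[s] <- TRUE
      amp[s] <- 0
    } else {
      amp[s] <- pk$y
      t_on <- crossing_time(seg[seq_len(ipk)], 0.05 * pk$y, 0, dt)
      lat[s] <- t_on # onset time relative to AP peak
    }
  }
  m <- mean(amp)
  s2 <- stats::sd(amp)
  m2 <- mean((amp - m)^2)
  m3 <- mean((amp - m)^3)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  lat_ok <- lat[!fail & !is.na(lat)]
  latency_defined <- length(lat_ok) > 0L
  # decay from the average of non-failure trials
  decay <- NA_real_
  if (any(!fail)) {
    avg <- rowMeans(sweeps$sweeps[, !fail, drop = FALSE]) * sgn
    decay <- tryCatch(decay_fit(avg, dt)$tau, error = function(e) NA_real_)
  }
  structure(list(
    mean_amplitude = m, failure_fraction = mean(fail),
    cv = if (m != 0) s2 / m else NA_real_, skewness = skew,
    latency_mean = if (latency_defined) mean(lat_ok) else NA_real_,
    latency_sd = if (length(lat_ok) > 1L) stats::sd(lat_ok) else
      if (latency_defined) 0 else NA_real_,
    latency_defined = latency_defined,
    decay_tau = decay, direction = sgn,
    amplitudes = amp, latencies = lat, failures = fail),
    class = "unitary_stats")
}

#' @export
print.unitary_stats <- function(x, ...) {
  cat(sprintf(
    "<unitary_stats> mean %.1f pA, failures %.1f%%, CV %.2f, skew %.2f, latency %.3g +/- %.3g ms\n",
    x$mean_amplitude, 100 * x$failure_fraction, x$cv, x$skewness,
    x$latency_mean, x$latency_sd))
  invisible(x)
}

#' Align sweeps and average
#'
#' Sub-sample alignment by linear interpolation, either to the presynaptic
#' AP peak (`"ap_peak"`; preserves ensemble latency) or to the 50% rise
#' point of each trial (`"half_rise"`; removes latency jitter, the standard
#' alignment for building a quantal waveform).
#'
#' @param sweeps A [sweep_set()].
#' @param mode `"ap_peak"` or `"half_rise"`.
#' @param window Response search window (ms after AP) for the half-rise
#'   detection.
#' @param failure_k Trials failing at this threshold are excluded in
#'   `half_rise` mode (error if all fail).
#' @return A list: `trace` (averaged, aligned trace), `t` (time in ms,
#'   0 = alignment point), `dt`, `n_used`.
#' @export
align_and_average <- function(sweeps, mode = c("ap_peak", "half_rise"),
                              window = 20, failure_k = 3) {
  stopifnot(inherits(sweeps, "sweep_set"))
  mode <- match.arg(mode)
  dt <- sweeps$dt
  n <- nrow(sweeps$sweeps)
  n_tr <- ncol(sweeps$sweeps)
  sgn <- detect_direction(sweeps)
  ref <- numeric(n_tr)
  use <- rep(TRUE, n_tr)
  for (s in seq_len(n_tr)) {
    ap <- sweeps$ap_times[[s]][1L]
    if (mode == "ap_peak") {
      ref[s] <- ap
      next
    }
    y <- sgn * sweeps$sweeps[, s]
    i_ap <- round(ap / dt) + 1L
    b2 <- max(1L, i_ap - round(0.5 / dt))
    b1 <- max(1L, i_ap - round(2.5 / dt))
    base <- mean(y[b1:b2])
    base_sd <- stats::sd(y[b1:b2])
    i_end <- min(n, i_ap + round(window / dt))
    seg <- y[i_ap:i_end] - base
    ipk <- which.max(seg)
    if (!response_detected(seg, dt, failure_k, base_sd)) {
      use[s] <- FALSE
      next
    }
    t50 <- crossing_time(seg[seq_len(ipk)], 0.5 * seg[ipk], 0, dt)
    ref[s] <- if (is.na(t50)) ap else ap + t50
  }
  if (!any(use)) stop_invalid("all trials are failures; cannot align to half-rise")
  t_rel_min <- -min(ref[use])
  t_rel_max <- (n - 1L) * dt - max(ref[use])
  t_out <- seq(ceiling(t_rel_min / dt) * dt, floor(t_rel_max / dt) * dt, by = dt)
  acc <- numeric(length(t_out))
  t_in <- (seq_len(n) - 1L) * dt
  for (s in which(use)) {
    acc <- acc + stats::approx(t_in - ref[s], sweeps$sweeps[, s],
                               xout = t_out, rule = 2)$y
  }
  list(trace = acc / sum(use), t = t_out, dt = dt, n_used = sum(use))
}

#' Per-stimulus IPSC amplitudes in a train
#'
#' Sweeps are averaged and each IPSC amplitude is measured from the baseline
#' directly preceding its rising phase (mean over a 1 ms window ending at
#' the AP peak) to the peak within the following inter-stimulus interval.
#'
#' @param sweeps A [sweep_set()] (all sweeps share the same AP times).
#' @param baseline_ms Pre-stimulus baseline window (ms).
#' @return An object of class `train_amplitudes`: `amplitudes` (pA, one per
#'   stimulus, positive), `normalized` (divided by the first amplitude),
#'   `ap_times`, `isi` (ms).
#' @export
measure_train <- function(sweeps, baseline_ms = 1) {
  stopifnot(inherits(sweeps, "sweep_set"))
  ap <- sweeps$ap_times[[1L]]
  if (length(ap) < 2L) stop_invalid("need >= 2 stimuli")
  dt <- sweeps$dt
  isi <- diff(ap)
  if (any(isi < 2)) stop_invalid("stimulus rate > 500 Hz: windows overlap")
  sgn <- detect_direction(sweeps)
  avg <- sgn * rowMeans(sweeps$sweeps)
  n <- length(avg)
  k <- length(ap)
  amps <- numeric(k)
  for (i in seq_len(k)) {
    i_ap <- round(ap[i] / dt) + 1L
    b1 <- max(1L, i_ap - round(baseline_ms / dt))
    base <- mean(avg[b1:i_ap])
    i_end <- if (i < k) round(ap[i + 1L] / dt) else min(n, i_ap + round(mean(isi) / dt))
    seg <- avg[i_ap:min(i_end, n)]
    pk <- refine_peak(seg, which.max(seg), 0, dt)
    amps[i] <- pk$y - base
  }
  structure(list(amplitudes = amps, normalized = amps / amps[1L],
                 ap_times = ap, isi = mean(isi)),
            class = "train_amplitudes")
}

#' @export
print.train_amplitudes <- function(x, ...) {
  k <- length(x$amplitudes)
  cat(sprintf(
    "<train_amplitudes> %d stimuli @ %.3g ms ISI; IPSC1 %.1f pA, IPSC%d/IPSC1 = %.2f\n",
    k, x$isi, x$amplitudes[1L], k, x$normalized[k]))
  invisible(x)
}

#' Mono-exponential decay fit
#'
#' Fits \eqn{y(t) = A e^{-t/\tau}} to the decay phase of an averaged
#' response, from `offset_ms` after the peak until the trace first returns
#' to `baseline_frac` of the peak (or the end of the trace).  Initialized by
#' a log-linear regression and refined by Gauss-Newton (`nls`).
#'
#' @param trace Numeric averaged trace (baseline-subtracted; either sign).
#' @param dt Sampling interval (ms).
#' @param offset_ms Fit start after the peak (ms).
#' @param baseline_frac Fit end where the trace reaches this fraction of
#'   the peak (default 0.05).
#' @return List with `tau` (ms), `amplitude` (pA at fit start, signed like
#'   the input), and `n_points`.  Errors with a fit-failure message for a
#'   flat or non-decaying trace.
#' @export
decay_fit <- function(trace, dt, offset_ms = 0, baseline_frac = 0.05) {
  sgn <- if (abs(min(trace)) > abs(max(trace))) -1 else 1
  y <- sgn * trace
  ipk <- which.max(y)
  pk <- y[ipk]
  if (!is.finite(pk) || pk <= 0 || stats::sd(y) == 0)
    stop_invalid("decay fit failed: no identifiable peak")
  i0 <- ipk + round(offset_ms / dt)
  below <- which(y[i0:length(y)] <= baseline_frac * pk)
  i1 <- if (length(below)) i0 + below[1L] - 1L else length(y)
  if (i1 - i0 < 5L) stop_invalid("decay fit failed: too few points after peak")
  seg <- y[i0:i1]
  tt <- (seq_along(seg) - 1L) * dt
  pos <- seg > 0
  if (sum(pos) < 5L) stop_invalid("decay fit failed: trace not positive after peak")
  lf <- stats::lm(log(seg[pos]) ~ tt[pos])
  slope <- stats::coef(lf)[[2L]]
  if (slope >= 0) stop_invalid("decay fit failed: trace does not decay")
  tau0 <- -1 / slope
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(seg ~ A * exp(-tt / tau),
                 start = list(A = seg[1L], tau = tau0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- tau0
    A <- exp(stats::coef(lf)[[1L]])
  } else {
    tau <- stats::coef(fit)[["tau"]]
    A <- stats::coef(fit)[["A"]]
  }
  if (!is.finite(tau) || tau <= 0) stop_invalid("decay fit failed")
  list(tau = tau, amplitude = sgn * A, n_points = length(seg))
}

#' Peak conductance from peak current
#'
#' \eqn{G = I / (V_{hold} - E_{rev})}, reported as a magnitude.  With I in
#' pA and V in mV the result is in nS.
#'
#' @param peak_current Peak current (pA, signed).
#' @param holding Holding potential (mV).
#' @param reversal Reversal potential of the conductance (mV).
#' @return Conductance magnitude in nS.
#' @export
conductance_from_current <- function(peak_current, holding, reversal) {
  if (any(holding == reversal))
    stop_invalid("holding potential equals reversal potential")
  abs(peak_current / (holding - reversal))
}

#' Excitation-inhibition delay (peak to peak)
#'
#' Delay from the EPSC peak (recorded at the inhibitory reversal) to the
#' IPSC peak (recorded at the excitatory reversal); both peaks are
#' parabola-refined.  The IPSC must exceed `k` baseline SDs, otherwise the
#' delay is flagged undefined.
#'
#' @param epsc,ipsc Numeric traces (pA) on a common time base.
#' @param dt Sampling interval (ms).
#' @param k Detection threshold for the IPSC in baseline SDs.
#' @param baseline_n Samples used for the IPSC baseline SD (default first
#'   10% of the trace).
#' @return List: `delay` (ms, `NA` when undefined), `defined`,
#'   `epsc_peak_time`, `ipsc_peak_time` (ms).
#' @export
ei_delay <- function(epsc, ipsc, dt, k = 3, baseline_n = NULL) {
  pk_of <- function(y) {
    sgn <- if (abs(min(y)) > abs(max(y))) -1 else 1
    refine_peak(sgn * y, which.max(sgn * y), 0, dt)
  }
  pe <- pk_of(epsc)
  baseline_n <- baseline_n %||% max(10L, round(length(ipsc) / 10))
  b_sd <- stats::sd(ipsc[seq_len(baseline_n)])
  ic <- ipsc - mean(ipsc[seq_len(baseline_n)])
  sgn_i <- if (abs(min(ic)) > abs(max(ic))) -1 else 1
  pi_ <- pk_of(ipsc - mean(ipsc[seq_len(baseline_n)]))
  if (b_sd > 0 && !response_detected(sgn_i * ic, dt, k, b_sd)) {
    return(list(delay = NA_real_, defined = FALSE,
                epsc_peak_time = pe$t, ipsc_peak_time = NA_real_))
  }
  list(delay = pi_$t - pe$t, defined = TRUE,
       epsc_peak_time = pe$t, ipsc_peak_time = pi_$t)
}
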