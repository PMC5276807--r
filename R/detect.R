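#' Template-matching configuration
#'
#' Settings for the scaled-template detector: at every offset the template
#' is fitted to the trace by least squares with free scale and baseline
#' offset, and the detection criterion is the fitted scale divided by its
#' standard error.  Local maxima of the criterion above `criterion_threshold`
#' separated by at least `refractory` become events.
#'
#' @param template Sampled template (numeric vector) or a
#'   [quantal_waveform()]; internally normalized to unit peak.
#' @param criterion_threshold Detection criterion threshold (> 0, default 4,
#'   common practice for this detector).
#' @param refractory Minimum inter-detection interval in ms (default 1).
#' @param direction `"negative"` for inward (downward) events — the usual
#'   IPSC polarity — or `"positive"`.
#' @param dt Sampling interval used to sample `template` when a
#'   [quantal_waveform()] is given (ms).
#' @param template_duration Duration of the sampled template (ms); default
#'   3 decay constants — long enough to constrain the fit, short enough to
#'   resolve closely spaced events.
#' @return An object of class `template_match_config`.
#' @export
template_match_config <- function(template, criterion_threshold = 4,
                                  refractory = 1,
                                  direction = c("negative", "positive"),
                                  dt = 0.05, template_duration = NULL) {
  direction <- match.arg(direction)
  if (criterion_threshold <= 0) stop_invalid("threshold must be > 0")
  if (refractory < 0) stop_invalid("refractory must be >= 0")
  if (inherits(template, "quantal_waveform")) {
    template_duration <- template_duration %||% (3 * template$tau_decay)
    template <- make_quantal_waveform(template, dt, template_duration,
                                      signed = FALSE)
  }
  template <- as.numeric(template) / max(abs(template))
  structure(list(template = template, criterion_threshold = criterion_threshold,
                 refractory = refractory, direction = direction),
            class = "template_match_config")
}

# Sliding least-squares fit of y ~ scale*template + offset at every lag.
# Returns scale, criterion = scale/SE(scale) for window starts 1..(n-m+1).
# All running sums are computed by cumulative sums and one FFT
# cross-correlation, so the scan is O(n log n).
sliding_template_fit <- function(y, template) {
  n <- length(y)
  m <- length(template)
  if (m >= n) stop_invalid("template must be shorter than the sweep")
  St <- sum(template)
  Stt <- sum(template^2)
  denom_t <- Stt - St^2 / m
  cy <- c(0, cumsum(y))
  cy2 <- c(0, cumsum(y^2))
  nw <- n - m + 1L
  Sy <- cy[(m + 1L):(n + 1L)] - cy[1L:nw]
  Syy <- cy2[(m + 1L):(n + 1L)] - cy2[1L:nw]
  # cross-correlation sum_j template[j] * y[i+j-1] via FFT convolution
  L <- stats::nextn(n + m, 2L)
  Y <- stats::fft(c(y, numeric(L - n)))
  Tk <- stats::fft(c(rev(template), numeric(L - m)))
  xc <- Re(stats::fft(Y * Tk, inverse = TRUE)) / L
  Sty <- xc[m:(m + nw - 1L)]
  scale <- (Sty - St * Sy / m) / denom_t
  offset <- (Sy - scale * St) / m
  sse <- Syy + scale^2 * Stt + m * offset^2 -
    2 * scale * Sty - 2 * offset * Sy + 2 * scale * offset * St
  sse[sse < 0] <- 0
  se <- sqrt(sse / (m - 2)) / sqrt(denom_t)
  crit <- ifelse(se > 0, scale / se, 0)
  list(scale = scale, offset = offset, criterion = crit, m = m)
}

#' Detect miniature events by sliding-template matching
#'
#' @param sweep A [sweep_set()] (each sweep scanned independently) or a
#'   numeric trace.
#' @param cfg A [template_match_config()].
#' @param dt Sampling interval in ms (taken from the sweep set when given).
#' @return An `event_table`: data.frame with one row per event — `sweep`,
#'   `time` (ms, event onset = template start at the criterion peak),
#'   `peak_time` (ms, parabola-refined), `amplitude` (pA, baseline-to-peak,
#'   positive), `rise_time_20_80` (ms), `criterion`, and `overlapping`
#'   (TRUE when the previous detection lies within one template length —
#'   superimposed events are retained and flagged).  Attributes: `duration`
#'   (s, summed over sweeps) and `dt`.
#' @export
template_match <- function(sweep, cfg, dt = NULL) {
  stopifnot(inherits(cfg, "template_match_config"))
  if (inherits(sweep, "sweep_set")) {
    dt <- sweep$dt
    traces <- sweep$sweeps
  } else {
    if (is.null(dt)) stop_invalid("dt required for a bare numeric trace")
    traces <- matrix(sweep, ncol = 1L)
  }
  sgn <- if (cfg$direction == "negative") -1 else 1
  rows <- list()
  for (s in seq_len(ncol(traces))) {
    y <- sgn * traces[, s]
    if (stats::sd(y) == 0) {
      warning("flat (zero-variance) sweep; no events detected")
      next
    }
    fit <- sliding_template_fit(y, cfg$template)
    crit <- fit$criterion
    # studentize: under band-limited noise the residuals are correlated and
    # the nominal SE underestimates the criterion spread; rescaling by the
    # robust (MAD) SD keeps the threshold in true noise-SD units.  The MAD
    # is insensitive to the sparse event-related excursions.
    crit_sd <- stats::mad(crit, center = 0)
    if (is.finite(crit_sd) && crit_sd > 0) crit <- crit / crit_sd
    nw <- length(crit)
    kept <- detect_peaks(crit, cfg$criterion_threshold,
                         max(1L, round(cfg$refractory / dt)))
    for (i in kept) {
      meas <- measure_event(y, i, fit$m, dt)
      rows[[length(rows) + 1L]] <- data.frame(
        sweep = s, time = (i - 1L) * dt, peak_time = meas$peak_time,
        amplitude = meas$amplitude, rise_time_20_80 = meas$rise,
        criterion = crit[i],
        overlapping = FALSE)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sweep = integer(0), time = numeric(0), peak_time = numeric(0),
               amplitude = numeric(0), rise_time_20_80 = numeric(0),
               criterion = numeric(0), overlapping = logical(0))
  if (nrow(ev) > 1L) {
    tmpl_ms <- length(cfg$template) * dt
    same <- c(FALSE, diff(ev$time) < tmpl_ms & diff(ev$sweep) == 0)
    ev$overlapping <- same | c(same[-1L], FALSE)
  }
  attr(ev, "duration") <- ncol(traces) * nrow(traces) * dt / 1000
  attr(ev, "dt") <- dt
  class(ev) <- c("event_table", "data.frame")
  ev
}

# One detection per contiguous above-threshold run of the criterion, at the
# run's maximum; runs separated by less than the refractory interval are
# merged.  A run spans the whole passage of the template across an event
# (roughly one template length), which sets the detector's resolution for
# superimposed events — closer events merge into one detection.
detect_peaks <- function(crit, threshold, ref_samp) {
  above <- crit >= threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  # merge sub-refractory gaps between consecutive above-threshold runs
  runs <- cbind(starts[ok], ends[ok])
  merged <- list()
  cur <- runs[1L, ]
  for (j in seq_len(nrow(runs))[-1L]) {
    if (runs[j, 1L] - cur[2L] < ref_samp) {
      cur[2L] <- runs[j, 2L]
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- runs[j, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  vapply(merged, function(ab) {
    as.integer(ab[1L]) - 1L + which.max(crit[ab[1L]:ab[2L]])
  }, integer(1L))
}

# Baseline, amplitude, and 20-80% rise time of one detected event on the
# rectified trace y (event upward).  i = detection (window-start) index.
measure_event <- function(y, i, m, dt) {
  n <- length(y)
  # baseline: 2 ms window ending 0.5 ms before detection
  b1 <- max(1L, i - round(2.5 / dt))
  b2 <- max(1L, i - round(0.5 / dt))
  baseline <- mean(y[b1:b2])
  p2 <- min(n, i + m - 1L)
  seg <- y[i:p2]
  ipk <- which.max(seg)
  pk <- refine_peak(seg, ipk, (i - 1L) * dt, dt)
  amplitude <- pk$y - baseline
  # 20-80% rise between baseline-crossing levels before the peak
  lev20 <- baseline + 0.2 * amplitude
  lev80 <- baseline + 0.8 * amplitude
  pre <- y[i:(i + ipk - 1L)]
  t20 <- crossing_time(pre, lev20, (i - 1L) * dt, dt)
  t80 <- crossing_time(pre, lev80, (i - 1L) * dt, dt)
  rise <- if (is.na(t20) || is.na(t80)) NA_real_ else t80 - t20
  list(amplitude = amplitude, peak_time = pk$t, rise = rise)
}

# Last upward crossing of `level` before the end of seg, linearly
# interpolated between samples.
crossing_time <- function(seg, level, t0, dt) {
  below <- which(seg < level)
  if (!length(below) || below[length(below)] >= length(seg)) return(NA_real_)
  j <- below[length(below)]
  f <- (level - seg[j]) / (seg[j + 1L] - seg[j])
  t0 + (j - 1L + f) * dt
}

#' Summary statistics of a detected-event table
#'
#' @param events An `event_table` from [template_match()].
#' @param duration Recording duration in s (defaults to the table's
#'   `duration` attribute).
#' @return A list: `n_events`, `frequency_hz` (= count/duration),
#'   `mean_amplitude_pa`, `median_amplitude_pa`, `mean_rise_ms`, and `iei_ms`
#'   (inter-event intervals, successive differences within each sweep).
#' @export
event_statistics <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration")
  if (is.null(duration) || duration <= 0) stop_invalid("duration must be > 0")
  iei <- unlist(lapply(split(events$time, events$sweep), diff), use.names = FALSE)
  list(n_events = nrow(events),
       frequency_hz = nrow(events) / duration,
       mean_amplitude_pa = if (nrow(events)) mean(events$amplitude) else NA_real_,
       median_amplitude_pa = if (nrow(events)) stats::median(events$amplitude) else NA_real_,
       mean_rise_ms = if (nrow(events)) mean(events$rise_time_20_80, na.rm = TRUE) else NA_real_,
       iei_ms = iei %||% numeric(0))
}

#' Restrict an event table to fast-rising events
#'
#' Keeps events with a 20--80% rise time strictly below `cutoff`; at a
#' somatically recorded cell this isolates perisomatic (proximal) inputs.
#'
#' @param events An `event_table`.
#' @param cutoff Rise-time cutoff in ms (strict inequality).
#' @return The filtered `event_table`, order preserved.
#' @export
subset_by_rise_time <- function(events, cutoff = 1.5) {
  keep <- !is.na(events$rise_time_20_80) & events$rise_time_20_80 < cutoff
  out <- events[keep, , drop = FALSE]
  attr(out, "duration") <- attr(events, "duration")
  attr(out, "dt") <- attr(events, "dt")
  class(out) <- class(events)
  out
}

#' Write an event table, and cumulative inter-event-interval histogram, as CSV
#'
#' @param events An `event_table`.
#' @param path Output CSV path for the table.
#' @param iei_path Optional path for a two-column (`iei_ms`,
#'   `cumulative_fraction`) CSV of the IEI distribution.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path, iei_path = NULL) {
  df <- as.data.frame(events)
  names(df) <- c("sweep", "time_ms", "peak_time_ms", "amplitude_pa",
                 "rise_time_20_80_ms", "criterion", "overlapping")
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(iei_path)) {
    iei <- sort(event_statistics(events)$iei_ms)
    utils::write.csv(data.frame(iei_ms = iei,
                                cumulative_fraction = seq_along(iei) / length(iei)),
                     iei_path, row.names = FALSE)
  }
  invisible(path)
}
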