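#' Simulate binomial release from a depleting, replenishing pool
#'
#' For each sweep the vesicle pool starts full at N.  At every AP the
#' released count is drawn as Binomial(current pool, Pr); the pool is
#' decremented by the released count and then, over the interval to the next
#' AP, incremented by `replenish_rate * interval` (stochastically rounded so
#' the expectation is exact) and capped at N.
#'
#' @param model A [release_model()].
#' @param ap_times Strictly increasing AP peak times in ms (non-empty).
#' @param n_sweeps Number of independent sweeps (>= 1).
#' @param seed Integer seed; identical seeds and parameters give
#'   bit-identical ground truth.  Per-sweep substreams are derived from the
#'   seed and the sweep index, so extending `n_sweeps` never perturbs
#'   earlier sweeps.
#' @return An object of class `release_ground_truth`: per sweep, the
#'   released count per AP (`counts`, n_sweeps x n_ap matrix), the pool
#'   occupancy immediately before each AP (`pool_before`), plus the inputs.
#'   Release *times* are attached later by [draw_release_times()].
#' @export
simulate_pool_train <- function(model, ap_times, n_sweeps = 1L, seed = NULL) {
  stopifnot(inherits(model, "release_model"))
  if (length(ap_times) == 0L) stop_invalid("ap_times must be non-empty")
  if (is.unsorted(ap_times, strictly = TRUE))
    stop_invalid("ap_times must be strictly increasing")
  if (n_sweeps < 1L) stop_invalid("n_sweeps must be >= 1")
  n_ap <- length(ap_times)
  counts <- matrix(0L, n_sweeps, n_ap)
  pool_before <- matrix(0L, n_sweeps, n_ap)
  intervals <- diff(ap_times)
  for (s in seq_len(n_sweeps)) {
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, s), {
      pool <- model$pool_size
      for (i in seq_len(n_ap)) {
        pool_before[s, i] <- pool
        k <- stats::rbinom(1L, pool, model$release_prob)
        counts[s, i] <- k
        pool <- pool - k
        if (i < n_ap) {
          pool <- min(pool + stochastic_round(model$replenish_rate * intervals[i]),
                      model$pool_size)
        }
      }
    })
  }
  structure(list(counts = counts, pool_before = pool_before,
                 ap_times = as.numeric(ap_times), model = model,
                 seed = seed, release = NULL),
            class = "release_ground_truth")
}

#' @export
print.release_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<release_ground_truth> %d sweep(s) x %d AP(s); mean released/AP %.2f%s\n",
    nrow(x$counts), ncol(x$counts), mean(x$counts),
    if (is.null(x$release)) " (times not drawn)" else ""))
  invisible(x)
}

#' Draw tagged release times for simulated release counts
#'
#' Every synchronously released quantum receives a latency drawn from the
#' model's release-time density (relative to its AP peak).  Asynchronous
#' quanta are added as an inhomogeneous Poisson process: constant rate
#' `async_rate_train` from the first AP to one mean interval after the last
#' AP, then `async_rate_post * exp(-t/async_post_tau)` after the train.
#'
#' @param truth A `release_ground_truth` from [simulate_pool_train()].
#' @param model Optional [release_model()] overriding the one stored in
#'   `truth`.
#' @param seed Integer seed for the latency/asynchronous draws.
#' @param t_max Truncate release times beyond this (ms); default `Inf`.
#' @return `truth` with `$release`: one data.frame per sweep with columns
#'   `time` (ms), `tag` (`"synchronous"`, `"asynchronous"`), `ap_index`
#'   (NA for asynchronous quanta), and `amp_factor` (lognormal per-quantum
#'   amplitude factor, mean 1, CV `quantal_cv`).
#' @export
draw_release_times <- function(truth, model = NULL, seed = NULL, t_max = Inf) {
  stopifnot(inherits(truth, "release_ground_truth"))
  model <- model %||% truth$model
  tcr <- tcr_density(model$tcr_family, model$tcr_latency,
                     model$tcr_half_duration)
  n_sweeps <- nrow(truth$counts)
  ap <- truth$ap_times
  mean_isi <- if (length(ap) > 1L) mean(diff(ap)) else 10
  train_end <- ap[length(ap)] + mean_isi
  sigma_ln <- sqrt(log(1 + model$quantal_cv^2))
  release <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    release[[s]] <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, s + 104729L), {
      times <- numeric(0); tag <- character(0); ap_idx <- integer(0)
      for (i in seq_along(ap)) {
        k <- truth$counts[s, i]
        if (k > 0L) {
          lat <- tcr$r(k)
          while (any(lat < 0)) lat[lat < 0] <- tcr$r(sum(lat < 0))
          times <- c(times, ap[i] + lat)
          tag <- c(tag, rep("synchronous", k))
          ap_idx <- c(ap_idx, rep(i, k))
        }
      }
      if (model$async_rate_train > 0) {
        span <- train_end - ap[1L]
        n_async <- stats::rpois(1L, model$async_rate_train * span)
        if (n_async > 0L) {
          times <- c(times, stats::runif(n_async, ap[1L], train_end))
          tag <- c(tag, rep("asynchronous", n_async))
          ap_idx <- c(ap_idx, rep(NA_integer_, n_async))
        }
      }
      if (model$async_rate_post > 0) {
        # rate r0 exp(-t/tau) after train end: total mass r0*tau, inverse CDF
        mass <- model$async_rate_post * model$async_post_tau
        n_post <- stats::rpois(1L, mass)
        if (n_post > 0L) {
          u <- stats::runif(n_post)
          times <- c(times, train_end - model$async_post_tau * log(1 - u))
          tag <- c(tag, rep("asynchronous", n_post))
          ap_idx <- c(ap_idx, rep(NA_integer_, n_post))
        }
      }
      keep <- times <= t_max
      amp <- exp(stats::rnorm(sum(keep), -sigma_ln^2 / 2, sigma_ln))
      ord <- order(times[keep])
      data.frame(time = times[keep][ord], tag = tag[keep][ord],
                 ap_index = ap_idx[keep][ord], amp_factor = amp[ord])
    })
  }
  truth$release <- release
  truth
}

#' Per-stimulus amplitude matrix from ground-truth release times
#'
#' Sums the per-quantum amplitude factors of the synchronous quanta of each
#' AP and scales by the quantal amplitude: the idealized per-stimulus IPSC
#' amplitude, free of waveform-overlap measurement effects.  This is the
#' bridge between simulator ground truth and the pool-analysis functions
#' ([cumulative_pool_analysis()], [fluctuation_analysis()]).
#'
#' @param truth A `release_ground_truth` with drawn release times.
#' @param quantal_amplitude Quantal amplitude in pA (default 100).
#' @return Numeric matrix (sweeps x APs) of amplitudes in pA.
#' @export
amplitude_matrix <- function(truth, quantal_amplitude = 100) {
  stopifnot(inherits(truth, "release_ground_truth"))
  if (is.null(truth$release))
    stop_invalid("release times missing; call draw_release_times() first")
  n_sweeps <- nrow(truth$counts)
  n_ap <- ncol(truth$counts)
  amp <- matrix(0, n_sweeps, n_ap)
  for (s in seq_len(n_sweeps)) {
    rel <- truth$release[[s]]
    syn <- rel[rel$tag == "synchronous", ]
    if (nrow(syn)) {
      agg <- tapply(syn$amp_factor,
                    factor(syn$ap_index, levels = seq_len(n_ap)),
                    sum, default = 0)
      amp[s, ] <- as.numeric(agg) * quantal_amplitude
    }
  }
  amp
}

#' Render current sweeps from ground-truth release times
#'
#' Each quantum contributes the quantal kernel shifted to its release time
#' (sub-sample placement by linear interpolation) and scaled by its
#' amplitude factor; band-limited Gaussian noise is added on top.
#'
#' @param truth A `release_ground_truth` with release times
#'   ([draw_release_times()]).
#' @param q A [quantal_waveform()] or a sampled kernel (numeric vector, pA,
#'   starting at the quantum onset).
#' @param noise A [noise_model()] or `NULL` for noiseless traces.
#' @param dt Sampling interval in ms (default 0.02, i.e. 50 kHz).
#' @param duration Trace duration in ms; default covers the last release
#'   plus ten kernel decay constants.
#' @param seed Integer seed for the noise draws.
#' @param condition,holding_potential Metadata passed to [sweep_set()].
#' @return A [sweep_set()].
#' @export
render_sweeps <- function(truth, q, noise = NULL, dt = 0.02, duration = NULL,
                          seed = NULL, condition = "",
                          holding_potential = -70) {
  stopifnot(inherits(truth, "release_ground_truth"))
  if (is.null(truth$release))
    stop_invalid("release times missing; call draw_release_times() first")
  tail_ms <- if (inherits(q, "quantal_waveform")) 10 * q$tau_decay else 50
  if (is.null(duration)) {
    last <- max(c(truth$ap_times,
                  unlist(lapply(truth$release, function(r) r$time))))
    duration <- last + tail_ms
  }
  n <- round(duration / dt)
  kernel <- make_quantal_waveform(q, dt, min(duration, tail_ms))
  n_sweeps <- length(truth$release)
  sweeps <- matrix(0, n, n_sweeps)
  for (s in seq_len(n_sweeps)) {
    r <- truth$release[[s]]
    tr <- numeric(n)
    if (nrow(r)) {
      d <- frac_delta(r$time, dt, n)
      w <- numeric(n)
      # frac_delta drops out-of-range events; keep matching amplitude factors
      keep <- floor(r$time / dt) + 1 >= 1 & floor(r$time / dt) + 1 <= n
      af <- r$amp_factor[keep]
      for (j in seq_along(d$i1)) {
        w[d$i1[j]] <- w[d$i1[j]] + af[j] * d$w1[j]
        w[d$i2[j]] <- w[d$i2[j]] + af[j] * d$w2[j]
      }
      tr <- fft_conv(w, kernel)
    }
    if (!is.null(noise) && noise$sd > 0) {
      tr <- tr + with_seed(
        if (is.null(seed)) NULL else derive_seed(seed, s + 224737L),
        render_noise(noise, n, dt))
    }
    sweeps[, s] <- tr
  }
  sweep_set(sweeps, dt = dt, ap_times = rep(list(truth$ap_times), n_sweeps),
            condition = condition, holding_potential = holding_potential)
}

#' Simulate a spontaneous miniature-event sweep
#'
#' Event times form a homogeneous Poisson process of the given rate; each
#' event contributes one quantal waveform with lognormal amplitude jitter.
#'
#' @param rate Event rate in Hz (>= 0).
#' @param duration Sweep duration in s.
#' @param q A [quantal_waveform()].
#' @param noise A [noise_model()] or `NULL`.
#' @param dt Sampling interval in ms (default 0.05, i.e. 20 kHz — minis are
#'   slow enough that the lower acquisition rate is sufficient).
#' @param quantal_cv Amplitude CV (default 0.3).
#' @param seed Integer seed.
#' @return A list with `sweeps` (a [sweep_set()]) and `event_times` (true
#'   event onset times in ms).
#' @export
simulate_mini_sweep <- function(rate, duration, q, noise = NULL, dt = 0.05,
                                quantal_cv = 0.3, seed = NULL) {
  if (rate < 0) stop_invalid("rate must be >= 0")
  dur_ms <- duration * 1000
  ev <- with_seed(seed, {
    n_ev <- stats::rpois(1L, rate * duration)
    sort(stats::runif(n_ev, 0, dur_ms))
  })
  truth <- structure(list(
    counts = matrix(length(ev), 1L, 1L),
    pool_before = matrix(length(ev), 1L, 1L),
    ap_times = 0, model = NULL, seed = seed,
    release = list(local({
      sigma_ln <- sqrt(log(1 + quantal_cv^2))
      af <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 2L),
                      exp(stats::rnorm(length(ev), -sigma_ln^2 / 2, sigma_ln)))
      data.frame(time = ev, tag = rep("spontaneous", length(ev)),
                 ap_index = rep(NA_integer_, length(ev)), amp_factor = af)
    }))), class = "release_ground_truth")
  ss <- render_sweeps(truth, q, noise, dt = dt, duration = dur_ms,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 3L),
                      condition = "minis")
  ss$ap_times <- list(numeric(0))
  list(sweeps = ss, event_times = ev)
}

#' Simulate a pool-depletion train followed by a recovery test pulse
#'
#' A conditioning train (default 50 APs at 100 Hz) depletes the pool; after
#' each test interval a single AP probes refilling.  One sweep is produced
#' per interval; the pool recovers between train end and test AP under the
#' model's constant replenishment rate.
#'
#' @param model A [release_model()].
#' @param test_intervals Test intervals in ms (> 0), one sweep each.
#' @param n_train Conditioning APs (default 50).
#' @param freq_hz Train frequency (default 100 Hz).
#' @param seed Integer seed.
#' @return A `release_ground_truth` whose sweeps each contain
#'   `n_train + 1` APs (the last one is the test pulse); `$test_intervals`
#'   records the intervals.
#' @export
simulate_recovery_protocol <- function(model, test_intervals,
                                       n_train = 50L, freq_hz = 100,
                                       seed = NULL) {
  if (any(test_intervals <= 0)) stop_invalid("test intervals must be > 0")
  isi <- 1000 / freq_hz
  train <- (seq_len(n_train) - 1L) * isi
  n_int <- length(test_intervals)
  counts <- matrix(0L, n_int, n_train + 1L)
  pool_before <- matrix(0L, n_int, n_train + 1L)
  for (j in seq_len(n_int)) {
    ap <- c(train, train[n_train] + test_intervals[j])
    tr <- simulate_pool_train(model, ap, n_sweeps = 1L,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, j))
    counts[j, ] <- tr$counts
    pool_before[j, ] <- tr$pool_before
  }
  structure(list(counts = counts, pool_before = pool_before,
                 ap_times = train, test_intervals = as.numeric(test_intervals),
                 model = model, seed = seed, release = NULL),
            class = "release_ground_truth")
}

#' Render a feedforward-inhibition sweep
#'
#' The membrane current is the sum of an excitatory and a delayed inhibitory
#' conductance transient, each multiplied by its driving force:
#' \deqn{I(t) = g_E(t)(V - E_{exc}) + g_I(t - \Delta)(V - E_{inh}) + noise.}
#' Conductance transients use the same rise/decay product form as the
#' quantal waveform, scaled to the requested peak in nS; with V in mV the
#' current is in pA.
#'
#' @param exc,inh Lists with `peak` (nS), `tau_rise`, `tau_decay` (ms), and
#'   `onset` (ms); `inh = NULL` omits the inhibitory component.
#' @param delay Extra onset delay of the inhibitory conductance (ms).
#' @param holding Holding potential (mV).
#' @param reversal_exc,reversal_inh Reversal potentials (mV).
#' @param noise A [noise_model()] or `NULL`.
#' @param dt,duration Sampling interval and duration (ms).
#' @param seed Integer seed for the noise.
#' @return A [sweep_set()] with one sweep; attribute `conductances` holds
#'   the noiseless g_E and g_I traces (nS).
#' @export
render_ffi_sweep <- function(exc, inh = NULL, delay = 0, holding = -50,
                             reversal_exc = 0, reversal_inh = -85,
                             noise = NULL, dt = 0.02, duration = 100,
                             seed = NULL) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1L) * dt
  gtrans <- function(p, extra_delay = 0) {
    if (is.null(p)) return(numeric(n))
    on <- (p$onset %||% 0) + extra_delay
    tt <- pmax(t - on, 0)
    tpk <- p$tau_rise * log(1 + p$tau_decay / p$tau_rise)
    norm <- (1 - exp(-tpk / p$tau_rise)) * exp(-tpk / p$tau_decay)
    g <- p$peak / norm * (1 - exp(-tt / p$tau_rise)) * exp(-tt / p$tau_decay)
    g[t < on] <- 0
    g
  }
  gE <- gtrans(exc)
  gI <- gtrans(inh, delay)
  i_pA <- gE * (holding - reversal_exc) + gI * (holding - reversal_inh)
  if (!is.null(noise) && noise$sd > 0)
    i_pA <- i_pA + with_seed(seed, render_noise(noise, n, dt))
  ss <- sweep_set(i_pA, dt = dt, condition = "ffi",
                  holding_potential = holding)
  attr(ss, "conductances") <- list(g_exc = gE, g_inh = gI)
  ss
}
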