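#' Presynaptic release model
#'
#' Parameter set of the stochastic vesicle-pool model used by the synthetic
#' synapse generator: binomial release from a depleting pool with constant-
#' rate replenishment, per-quantum latency drawn from a parametric
#' release-time density, asynchronous Poisson release during and after the
#' train, spontaneous minis, and lognormal per-quantum amplitude jitter.
#'
#' @param pool_size Initial vesicle count N (non-negative integer).
#' @param release_prob Per-AP, per-vesicle release probability Pr in [0, 1].
#' @param replenish_rate Vesicles restored per ms between APs (pool capped
#'   at N; restored counts are stochastically rounded so the expectation is
#'   exact).
#' @param tcr_family,tcr_latency,tcr_half_duration Release-time density:
#'   family (`"gaussian"` or `"gamma"`), density-peak latency after the AP
#'   peak (ms), and FWHM (ms).  See [tcr_density()].
#' @param async_rate_train Asynchronous release rate during the train
#'   (quanta/ms).
#' @param async_rate_post Initial asynchronous rate after the last AP
#'   (quanta/ms), decaying exponentially with `async_post_tau` (ms).
#' @param async_post_tau Decay time constant of post-train asynchronous
#'   release (ms).
#' @param mini_rate Spontaneous miniature event rate (Hz).
#' @param quantal_cv Coefficient of variation of per-quantum amplitude
#'   (lognormal jitter with mean 1).  Default 0.3, a typical value for
#'   central synapses.
#' @return An object of class `release_model`.
#' @seealso [release_model_preset()] for parameter sets matching the
#'   wild-type, Syt2-rescue and Syt1-rescue phenotypes of the basket-cell
#'   to Purkinje-cell synapse.
#' @export
release_model <- function(pool_size = 44, release_prob = 0.2,
                          replenish_rate = 0.02,
                          tcr_family = "gaussian", tcr_latency = 1.17,
                          tcr_half_duration = 0.78,
                          async_rate_train = 0, async_rate_post = 0,
                          async_post_tau = 30, mini_rate = 0,
                          quantal_cv = 0.3) {
  if (pool_size < 0 || pool_size != round(pool_size))
    stop_invalid("pool_size must be a non-negative integer")
  if (release_prob < 0 || release_prob > 1)
    stop_invalid("release_prob must be in [0, 1]")
  if (replenish_rate < 0 || async_rate_train < 0 || async_rate_post < 0 ||
      mini_rate < 0 || quantal_cv < 0)
    stop_invalid("rates and quantal_cv must be non-negative")
  if (tcr_half_duration <= 0) stop_invalid("tcr_half_duration must be > 0")
  tcr <- tcr_density(tcr_family, tcr_latency, tcr_half_duration) # validates
  structure(list(pool_size = as.integer(pool_size),
                 release_prob = release_prob,
                 replenish_rate = replenish_rate,
                 tcr_family = tcr$family, tcr_latency = tcr_latency,
                 tcr_half_duration = tcr_half_duration,
                 async_rate_train = async_rate_train,
                 async_rate_post = async_rate_post,
                 async_post_tau = async_post_tau,
                 mini_rate = mini_rate, quantal_cv = quantal_cv),
            class = "release_model")
}

#' @export
print.release_model <- function(x, ...) {
  cat(sprintf(
    "<release_model> N=%d, Pr=%.3g, replenish %.3g /ms, TCR %s(latency %.3g ms, FWHM %.3g ms)\n",
    x$pool_size, x$release_prob, x$replenish_rate, x$tcr_family,
    x$tcr_latency, x$tcr_half_duration))
  invisible(x)
}

#' Named release-model presets
#'
#' Parameter sets describing the three synaptic phenotypes analysed in the
#' package's validation suite:
#'
#' * `"wild_type"`: high release probability, fast and temporally precise
#'   TCR (latency jitter SD 0.15 ms), mini rate 3.75 Hz.
#' * `"syt2_rescue"`: N = 44, Pr = 0.20, Gaussian TCR with latency 1.17 ms
#'   and half-duration 0.78 ms; replenishment matched to the steady-state
#'   depression level IPSC50/IPSC1 of about 0.56 during 100-Hz trains.
#' * `"syt1_rescue"`: N = 38, Pr = 0.22, Gaussian TCR with latency 1.64 ms
#'   and half-duration 2.00 ms; slower replenishment (IPSC50/IPSC1 of about
#'   0.21).
#' * `"syt2_rescue_pool"` / `"syt1_rescue_pool"`: same pools but with
#'   replenishment set from the post-train refill readout (RRP divided by
#'   the recovery time constant), the regime in which cumulative-amplitude
#'   back-extrapolation is approximately unbiased.  Used for
#'   parameter-recovery validation; see the methods vignette for why the
#'   within-train and post-train rates cannot be a single number in a
#'   constant-rate single-pool model.
#'
#' @param name Preset name.
#' @return A [release_model()].
#' @export
release_model_preset <- function(name = c("wild_type", "syt2_rescue",
                                          "syt1_rescue", "syt2_rescue_pool",
                                          "syt1_rescue_pool")) {
  name <- match.arg(name)
  switch(name,
    wild_type = release_model(
      pool_size = 44, release_prob = 0.21, replenish_rate = 0.425,
      tcr_family = "gaussian", tcr_latency = 0.65,
      tcr_half_duration = 0.15 * fwhm_sigma_factor(),
      mini_rate = 3.75),
    syt2_rescue = release_model(
      pool_size = 44, release_prob = 0.20, replenish_rate = 0.49,
      tcr_latency = 1.17, tcr_half_duration = 0.78),
    syt1_rescue = release_model(
      pool_size = 38, release_prob = 0.22, replenish_rate = 0.18,
      tcr_latency = 1.64, tcr_half_duration = 2.00),
    syt2_rescue_pool = release_model(
      pool_size = 44, release_prob = 0.20, replenish_rate = 0.0204,
      tcr_latency = 1.17, tcr_half_duration = 0.78),
    syt1_rescue_pool = release_model(
      pool_size = 38, release_prob = 0.22, replenish_rate = 0.0077,
      tcr_latency = 1.64, tcr_half_duration = 2.00))
}

#' Recording-noise model
#'
#' Band-limited Gaussian baseline noise: white noise is low-pass filtered at
#' `bandwidth` (Gaussian filter, half-amplitude corner) and rescaled so the
#' filtered trace has standard deviation `sd`.
#'
#' @param sd Baseline noise SD in pA (>= 0; 0 disables noise).
#' @param bandwidth Low-pass corner in kHz.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 2, bandwidth = 10) {
  if (sd < 0) stop_invalid("noise sd must be >= 0")
  if (bandwidth <= 0) stop_invalid("bandwidth must be > 0")
  structure(list(sd = sd, bandwidth = bandwidth), class = "noise_model")
}

# Sample one band-limited noise trace of n samples.
render_noise <- function(noise, n, dt) {
  if (is.null(noise) || noise$sd == 0) return(numeric(n))
  x <- stats::rnorm(n)
  y <- gaussian_lowpass(x, dt, noise$bandwidth)
  s <- stats::sd(y)
  if (s > 0) y <- y * (noise$sd / s)
  y
}
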