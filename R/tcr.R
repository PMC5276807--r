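#' Release-time (TCR) densities
#'
#' The time course of release (TCR) is the probability density of vesicle
#' release times relative to the presynaptic action-potential peak.  Two
#' families are supported, both parameterized by the location of the density
#' peak (`latency`, ms) and the full width at half maximum
#' (`half_duration`, ms):
#'
#' * `"gaussian"`: mean = mode = `latency`, sd = `half_duration / (2 sqrt(2 ln 2))`.
#' * `"gamma"`: shape `k` and scale `theta` are solved numerically so that
#'   the mode `(k - 1) theta` equals `latency` and the FWHM equals
#'   `half_duration` (requires `k > 1`, i.e. a finite positive mode).
#'
#' @param family `"gaussian"` or `"gamma"`.
#' @param latency Density peak in ms after the AP peak (> 0 for the gamma
#'   family).
#' @param half_duration FWHM in ms (> 0).
#' @return A list with the family, requested parameters, the native
#'   parameters (`mean`/`sd` or `shape`/`scale`), and closures `d(t)`
#'   (density) and `r(n)` (random draws).
#' @export
tcr_density <- function(family = c("gaussian", "gamma"), latency,
                        half_duration) {
  family <- match.arg(family)
  if (!is.finite(half_duration) || half_duration <= 0)
    stop_invalid("half_duration must be positive")
  if (family == "gaussian") {
    sd <- half_duration / fwhm_sigma_factor()
    return(list(family = family, latency = latency,
                half_duration = half_duration, mean = latency, sd = sd,
                d = function(t) stats::dnorm(t, latency, sd),
                r = function(n) stats::rnorm(n, latency, sd)))
  }
  if (!is.finite(latency) || latency <= 0)
    stop_invalid("gamma TCR requires latency > 0")
  par <- gamma_from_mode_fwhm(latency, half_duration)
  list(family = family, latency = latency, half_duration = half_duration,
       shape = par$shape, scale = par$scale,
       d = function(t) stats::dgamma(t, shape = par$shape, scale = par$scale),
       r = function(n) stats::rgamma(n, shape = par$shape, scale = par$scale))
}

# FWHM = 2 sqrt(2 ln 2) sigma for a Gaussian.
fwhm_sigma_factor <- function() 2 * sqrt(2 * log(2))

# FWHM of a gamma density with shape k, scale 1, in units of the scale.
# The mode is at k - 1; crossings of half the modal density are bracketed
# on either side and solved by uniroot.
gamma_fwhm_unit <- function(k) {
  mode <- k - 1
  ldens <- function(u) (k - 1) * log(u) - u
  lhalf <- ldens(mode) - log(2)
  f <- function(u) ldens(u) - lhalf
  # guaranteed left bracket: at u* = mode exp(-(log 2 + mode)/(k - 1)),
  # f(u*) = -u* < 0 (substitute into (k-1) log(u/mode) - (u - mode) + log 2)
  lower <- mode * exp(-(log(2) + mode) / (k - 1))
  if (lower == 0) lower <- .Machine$double.xmin
  lo <- stats::uniroot(f, lower = lower, upper = mode, tol = 1e-12)$root
  upper <- mode + 2
  while (f(upper) > 0) upper <- upper * 2
  hi <- stats::uniroot(f, lower = mode, upper = upper, tol = 1e-12)$root
  hi - lo
}

# Solve (shape, scale) of a gamma density from its mode and FWHM.
# fwhm/mode depends on shape only, and decreases monotonically with k.
gamma_from_mode_fwhm <- function(mode, fwhm) {
  target <- fwhm / mode
  g <- function(k) gamma_fwhm_unit(k) / (k - 1) - target
  # g(k) decreases monotonically; widen the bracket on both sides as needed
  lo <- 1.5
  while (g(lo) <= 0 && lo > 1 + 1e-9) lo <- 1 + (lo - 1) / 4
  hi <- 2
  while (g(hi) > 0 && hi < 1e9) hi <- hi^2
  k <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-12)$root
  list(shape = k, scale = mode / (k - 1))
}
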