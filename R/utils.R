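# Internal numerical helpers shared across modules.

#' @keywords internal
stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# Trapezoidal integral of y(t) over [a, b] with t uniform (t[1], dt);
# endpoints interpolated linearly so half-open windows integrate exactly.
trapz_window <- function(y, t0, dt, a, b) {
  n <- length(y)
  t_end <- t0 + (n - 1L) * dt
  a <- max(a, t0)
  b <- min(b, t_end)
  if (b <= a) return(0)
  yat <- function(x) {
    i <- (x - t0) / dt
    lo <- floor(i)
    f <- i - lo
    lo <- as.integer(lo) + 1L
    hi <- min(lo + 1L, n)
    (1 - f) * y[lo] + f * y[hi]
  }
  i0 <- ceiling((a - t0) / dt - 1e-9) + 1L # first grid index >= a
  i1 <- floor((b - t0) / dt + 1e-9) + 1L   # last grid index <= b
  if (i1 < i0) {
    return((b - a) * (yat(a) + yat(b)) / 2)
  }
  total <- trapz(y[i0:i1], dt)
  ta <- t0 + (i0 - 1L) * dt
  tb <- t0 + (i1 - 1L) * dt
  if (ta > a) total <- total + (ta - a) * (yat(a) + y[i0]) / 2
  if (tb < b) total <- total + (b - tb) * (y[i1] + yat(b)) / 2
  total
}

# Refine the position/height of a sampled extremum with a 3-point parabola.
# Returns list(t, y) in the same units as t0/dt; falls back to the sample
# when the point sits on a boundary or the parabola degenerates.
refine_peak <- function(y, idx, t0, dt) {
  n <- length(y)
  if (idx <= 1L || idx >= n) {
    return(list(t = t0 + (idx - 1L) * dt, y = y[idx]))
  }
  y1 <- y[idx - 1L]; y2 <- y[idx]; y3 <- y[idx + 1L]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(1, abs(y2))) {
    return(list(t = t0 + (idx - 1L) * dt, y = y2))
  }
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-0.5, min(0.5, d))
  list(t = t0 + (idx - 1L + d) * dt,
       y = y2 - 0.25 * (y1 - y3) * d)
}

# Linear convolution of x with kernel k via FFT; returns the first
# length(x) samples (kernel assumed causal, k[1] at lag 0).
fft_conv <- function(x, k) {
  n <- length(x)
  m <- length(k)
  L <- stats::nextn(n + m - 1L, 2L)
  xr <- c(x, numeric(L - n))
  kr <- c(k, numeric(L - m))
  out <- Re(stats::fft(stats::fft(xr) * stats::fft(kr), inverse = TRUE)) / L
  out[seq_len(n)]
}

# Zero-phase Gaussian low-pass with unit DC gain.  cutoff_khz is the
# -3 dB (half-amplitude) frequency in kHz; dt in ms.
gaussian_lowpass <- function(x, dt, cutoff_khz) {
  n <- length(x)
  if (n < 2L || !is.finite(cutoff_khz) || cutoff_khz <= 0) return(x)
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1L):1L)) / (n * dt) # cycles/ms = kHz
  sigma_f <- cutoff_khz / sqrt(2 * log(2))
  H <- exp(-f^2 / (2 * sigma_f^2))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

# Evaluate the RNG action `expr` under a derived seed without disturbing
# the caller's RNG stream.  seed = NULL leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Counter-based substream derivation: adding later units never perturbs
# the draws of earlier ones.  Keeps results within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Stochastic rounding: E[result] = x exactly.
stochastic_round <- function(x) {
  lo <- floor(x)
  as.integer(lo + (stats::runif(length(x)) < (x - lo)))
}

# Weighted two-tap delta placement for a sub-sample event time; returns
# integer indices and weights implementing linear interpolation of the
# kernel shifted to `time` (ms) on a grid starting at t = 0.
frac_delta <- function(time, dt, n) {
  i <- time / dt
  lo <- floor(i)
  f <- i - lo
  lo <- as.integer(lo) + 1L
  keep <- lo >= 1L & lo <= n
  list(i1 = lo[keep], i2 = pmin(lo[keep] + 1L, n),
       w1 = (1 - f[keep]), w2 = f[keep])
}

# Tiny FNV-1a hash of a character scalar; used for provenance stamps so
# the package needs no hashing dependency.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
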