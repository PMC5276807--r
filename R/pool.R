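# R^2 without summary.lm's perfect-fit warning.
rsq <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum((y - fitted)^2) / sst
}

#' Readily-releasable pool by cumulative-amplitude back-extrapolation
#'
#' Normalized IPSC amplitudes are cumulatively summed against stimulus
#' number; the last `last_k` points are fit by ordinary least squares.  The
#' intercept of the regression line with the ordinate estimates the pool in
#' units of IPSC1 (`rrp_norm`), the slope estimates replenishment per
#' stimulus (`refill_slope_norm`), and the release probability is
#' `1 / rrp_norm` (normalized IPSC1 over pool).  The estimate represents the
#' pool decrement: with ongoing replenishment it is biased low by roughly
#' the replenished fraction of the steady-state response — the bias is
#' reported by the validation suite, not corrected here.
#'
#' @param train A `train_amplitudes` from [measure_train()], or a numeric
#'   vector of per-stimulus amplitudes (normalized or raw).
#' @param last_k Number of final points in the regression (default 10).
#' @return An object of class `pool_estimate`: `rrp_norm`,
#'   `refill_slope_norm` (per stimulus), `pr`, `valid` (FALSE when the
#'   intercept is non-positive; `pr` is reported unclipped so biases stay
#'   visible), `r_squared`, `residuals`, `cumulative`, `isi` (ms, when
#'   known).  Absolute quantities are attached by [to_absolute()].
#' @export
cumulative_pool_analysis <- function(train, last_k = 10L) {
  if (inherits(train, "train_amplitudes")) {
    norm <- train$normalized
    isi <- train$isi
    ipsc1 <- train$amplitudes[1L]
  } else {
    norm <- as.numeric(train) / train[1L]
    isi <- NA_real_
    ipsc1 <- train[1L]
  }
  n <- length(norm)
  if (n <= last_k) stop_invalid("train length must exceed last_k")
  cum <- cumsum(norm)
  idx <- (n - last_k + 1L):n
  fit <- stats::lm(cum[idx] ~ idx)
  co <- stats::coef(fit)
  rrp_norm <- unname(co[1L])
  slope <- unname(co[2L])
  # intercepts that are zero to numerical precision mean pure replenishment
  valid <- rrp_norm > 1e-6 * max(abs(cum))
  structure(list(rrp_norm = rrp_norm, refill_slope_norm = slope,
                 pr = 1 / rrp_norm, valid = valid,
                 r_squared = rsq(cum[idx], stats::fitted(fit)),
                 residuals = unname(stats::resid(fit)),
                 cumulative = cum, last_k = last_k,
                 ipsc1_amplitude = ipsc1, isi = isi,
                 rrp_abs = NA_real_, refill_rate_abs = NA_real_,
                 quantal_size = NA_real_),
            class = "pool_estimate")
}

#' @export
print.pool_estimate <- function(x, ...) {
  cat(sprintf(
    "<pool_estimate> RRP %.2f x IPSC1 (Pr %.3f, refill %.3f/stim)%s%s\n",
    x$rrp_norm, x$pr, x$refill_slope_norm,
    if (is.finite(x$rrp_abs)) sprintf("; %.1f vesicles", x$rrp_abs) else "",
    if (!x$valid) " [INVALID: non-positive intercept]" else ""))
  invisible(x)
}

#' Quantal size by nonstationary fluctuation analysis
#'
#' Per-stimulus amplitude variance across sweeps is regressed (unconstrained
#' ordinary least squares) against the per-stimulus mean; the quantal size
#' is the slope of the fit line.  For binomial release the slope
#' underestimates the true quantal size by a factor of about (1 - Pr); the
#' bound is documented and measured in the validation suite.
#'
#' @param amplitudes Matrix of per-stimulus amplitudes (sweeps x stimuli,
#'   pA; at least 5 sweeps and 5 stimulus positions).
#' @return List: `quantal_size` (pA, the slope), `intercept`, `mean`,
#'   `variance` (per stimulus), `r_squared`, `valid` (FALSE for
#'   zero-variance data).
#' @export
fluctuation_analysis <- function(amplitudes) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) < 5L) stop_invalid("need >= 5 sweeps")
  if (ncol(amplitudes) < 5L) stop_invalid("need >= 5 stimulus positions")
  m <- colMeans(amplitudes)
  v <- apply(amplitudes, 2L, stats::var)
  if (length(unique(round(m, 12L))) < 3L)
    stop_invalid("need >= 3 distinct mean values")
  fit <- stats::lm(v ~ m)
  slope <- unname(stats::coef(fit)[2L])
  list(quantal_size = slope, intercept = unname(stats::coef(fit)[1L]),
       mean = m, variance = v, r_squared = rsq(v, stats::fitted(fit)),
       valid = any(v > 0) && slope > 0)
}

#' Convert a normalized pool estimate to absolute numbers
#'
#' The quantal content of IPSC1 is `ipsc1_amplitude / quantal_size`; the
#' normalized pool and refill slope are multiplied by it.  The refill rate
#' per ms divides the per-stimulus slope by the inter-stimulus interval
#' (this conversion convention is the package's own; see the methods
#' vignette).
#'
#' @param pool A `pool_estimate` from [cumulative_pool_analysis()].
#' @param ipsc1_amplitude Amplitude of the first IPSC in pA (defaults to the
#'   value stored in the estimate).
#' @param quantal_size Quantal size in pA (> 0), e.g. from
#'   [fluctuation_analysis()].
#' @param isi Inter-stimulus interval in ms (defaults to the stored value).
#' @return The `pool_estimate` with `rrp_abs` (vesicles),
#'   `refill_rate_abs` (quanta/ms), `quantal_size` and
#'   `quantal_content_ipsc1` filled in.
#' @export
to_absolute <- function(pool, ipsc1_amplitude = NULL, quantal_size, isi = NULL) {
  stopifnot(inherits(pool, "pool_estimate"))
  if (quantal_size <= 0) stop_invalid("quantal_size must be > 0")
  ipsc1 <- ipsc1_amplitude %||% pool$ipsc1_amplitude
  isi <- isi %||% pool$isi
  content1 <- ipsc1 / quantal_size
  pool$quantal_size <- quantal_size
  pool$quantal_content_ipsc1 <- content1
  pool$rrp_abs <- pool$rrp_norm * content1
  pool$refill_rate_abs <- if (is.finite(isi) && isi > 0)
    pool$refill_slope_norm * content1 / isi else NA_real_
  pool
}

#' Recovery from depression: exponential fit
#'
#' Fits \eqn{A(\Delta t) = A_\infty - (A_\infty - A_0)\, e^{-\Delta t/\tau}}
#' to test-pulse amplitudes (normalized to the first IPSC of the preceding
#' conditioning train) against the recovery interval.  All three parameters
#' are free.
#'
#' @param amplitudes Normalized test amplitudes.
#' @param intervals Recovery intervals in s (same length; >= 4 recommended,
#'   spanning at least twice the expected time constant).
#' @param rrp_abs Optional absolute pool size; when given, the post-train
#'   replenishment rate `rrp_abs / tau` (quanta/s) is reported.
#' @return An object of class `recovery_estimate`: `tau` (s), `asymptote`
#'   (A_inf), `depressed` (A_0), `replenish_after_train` (quanta/s or NA),
#'   `fitted`, `residuals`.
#' @export
recovery_fit <- function(amplitudes, intervals, rrp_abs = NULL) {
  if (length(amplitudes) != length(intervals) || length(amplitudes) < 3L)
    stop_invalid("need matching amplitudes and intervals (n >= 3)")
  if (stats::sd(amplitudes) == 0)
    stop_invalid("recovery fit failed: flat data, tau unidentifiable")
  a0 <- amplitudes[which.min(intervals)]
  ainf <- max(amplitudes)
  span <- ainf - a0
  if (span <= 0)
    stop_invalid("recovery fit failed: no recovery trend in data")
  tau0 <- max(intervals) / 3
  df <- data.frame(A = amplitudes, t = intervals)
  fit <- tryCatch(
    stats::nls(A ~ Ainf - (Ainf - A0) * exp(-t / tau), data = df,
               start = list(Ainf = ainf, A0 = a0, tau = tau0),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a tau grid search with linear profiling of (Ainf, A0)
    taus <- exp(seq(log(min(intervals[intervals > 0]) / 2),
                    log(max(intervals) * 10), length.out = 400))
    best <- NULL
    for (tau in taus) {
      x <- exp(-intervals / tau)
      lf <- stats::lm(amplitudes ~ x)
      sse <- sum(stats::resid(lf)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(sse = sse, tau = tau, co = stats::coef(lf))
    }
    if (is.null(best)) stop_invalid("recovery fit failed")
    sse_tau <- function(tau) {
      lf <- stats::lm(amplitudes ~ exp(-intervals / tau))
      sum(stats::resid(lf)^2)
    }
    opt <- stats::optimize(sse_tau, c(best$tau / 2, best$tau * 2),
                           tol = 1e-10)
    tau_f <- opt$minimum
    co <- stats::coef(stats::lm(amplitudes ~ exp(-intervals / tau_f)))
    ainf_f <- unname(co[1L])
    a0_f <- unname(co[1L] + co[2L])
    fitted <- ainf_f - (ainf_f - a0_f) * exp(-intervals / tau_f)
  } else {
    co <- stats::coef(fit)
    ainf_f <- co[["Ainf"]]; a0_f <- co[["A0"]]; tau_f <- co[["tau"]]
    fitted <- stats::fitted(fit)
  }
  if (!is.finite(tau_f) || tau_f <= 0)
    stop_invalid("recovery fit failed: non-positive time constant")
  structure(list(tau = tau_f, asymptote = ainf_f, depressed = a0_f,
                 replenish_after_train = if (is.null(rrp_abs)) NA_real_
                                         else rrp_abs / tau_f,
                 fitted = as.numeric(fitted),
                 residuals = amplitudes - as.numeric(fitted)),
            class = "recovery_estimate")
}

#' @export
print.recovery_estimate <- function(x, ...) {
  cat(sprintf(
    "<recovery_estimate> tau %.3g s, A0 %.2f -> Ainf %.2f%s\n",
    x$tau, x$depressed, x$asymptote,
    if (is.finite(x$replenish_after_train))
      sprintf(", replenishment %.1f quanta/s", x$replenish_after_train) else ""))
  invisible(x)
}
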