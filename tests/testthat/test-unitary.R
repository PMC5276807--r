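# Render n trials with one quantum each at AP time 10 ms plus a latency,
# with optional noise.  Returns a sweep_set whose AP time is 10 ms.
one_quantum_trials <- function(latencies, q = std_waveform("inward"),
                               noise = NULL, dt = 0.02, duration = 60,
                               seed = NULL, amp_factor = 1) {
  rel <- lapply(latencies, function(l) {
    if (is.na(l)) data.frame(time = numeric(0), amp_factor = numeric(0))
    else data.frame(time = 10 + l, amp_factor = amp_factor)
  })
  render_sweeps(manual_truth(rel, ap_times = 10), q, noise, dt = dt,
                duration = duration, seed = seed)
}

test_that("identical noiseless trials give zero CV, skewness and latency SD", {
  ss <- one_quantum_trials(rep(0.8, 4))
  st <- measure_unitary(ss)
  expect_equal(st$failure_fraction, 0)
  expect_equal(st$cv, 0, tolerance = 1e-9)
  expect_equal(st$skewness, 0, tolerance = 1e-6)
  expect_equal(st$latency_sd, 0, tolerance = 1e-9)
  expect_equal(st$mean_amplitude, 100, tolerance = 1)
})

test_that("failures count as zero amplitude and are excluded from latency", {
  ss <- one_quantum_trials(c(0.8, 0.8, NA, NA),
                           noise = noise_model(1, 10), seed = 5)
  st <- measure_unitary(ss)
  expect_equal(st$failure_fraction, 0.5)
  expect_equal(st$mean_amplitude, 50, tolerance = 3)
  expect_true(st$latency_defined)
  expect_identical(sum(is.na(st$latencies)), 2L)
  # all-failure ensembles keep amplitude stats but flag latency undefined
  ss0 <- one_quantum_trials(c(NA, NA), noise = noise_model(1, 10), seed = 6)
  st0 <- measure_unitary(ss0)
  expect_equal(st0$failure_fraction, 1)
  expect_equal(st0$mean_amplitude, 0)
  expect_false(st0$latency_defined)
  expect_true(is.na(st0$latency_mean))
})

test_that("CV and skewness match a direct moment oracle exactly", {
  set.seed(8)
  ss <- one_quantum_trials(rep(1, 12), noise = noise_model(2, 10), seed = 9,
                           amp_factor = 1)
  # vary amplitudes across trials via per-trial amp factors
  lat <- rep(1, 12)
  af <- exp(rnorm(12, 0, 0.25))
  rel <- lapply(seq_along(lat), function(i)
    data.frame(time = 10 + lat[i], amp_factor = af[i]))
  ss <- render_sweeps(manual_truth(rel, ap_times = 10),
                      std_waveform("inward"), noise_model(2, 10),
                      dt = 0.02, duration = 60, seed = 10)
  st <- measure_unitary(ss)
  a <- st$amplitudes
  expect_equal(st$cv, stats::sd(a) / mean(a), tolerance = 1e-12)
  m2 <- mean((a - mean(a))^2)
  m3 <- mean((a - mean(a))^3)
  expect_equal(st$skewness, m3 / m2^1.5, tolerance = 1e-12)
})

test_that("statistics are invariant to a constant baseline offset", {
  ss <- one_quantum_trials(c(0.7, 0.9, 1.1, 0.8),
                           noise = noise_model(2, 10), seed = 11)
  st <- measure_unitary(ss)
  ss_off <- ss
  ss_off$sweeps <- ss$sweeps - 37.5
  st_off <- measure_unitary(ss_off)
  expect_equal(st_off$amplitudes, st$amplitudes, tolerance = 1e-9)
  expect_equal(st_off$latencies, st$latencies, tolerance = 1e-9)
})

test_that("latency jitter is recovered from noisy ensembles", {
  errs <- vapply(1:5, function(s) {
    lat <- synquant:::with_seed(1000 + s, rnorm(50, 0.65, 0.15))
    ss <- one_quantum_trials(lat, noise = noise_model(5, 10),
                             seed = 2000 + s)
    st <- measure_unitary(ss)
    st$latency_sd
  }, 1)
  expect_lt(abs(mean(errs) - 0.15) / 0.15, 0.15)
})

test_that("failure classification is near-perfect at SNR >= 10", {
  m <- release_model(pool_size = 8, release_prob = 0.3, replenish_rate = 0,
                     tcr_latency = 1.17, tcr_half_duration = 0.78)
  truth <- simulate_pool_train(m, 10, n_sweeps = 100, seed = 21)
  truth <- draw_release_times(truth, seed = 22)
  ss <- render_sweeps(truth, std_waveform("inward"), noise_model(10, 10),
                      dt = 0.02, duration = 60, seed = 23)
  st <- measure_unitary(ss)
  truth_fail <- truth$counts[, 1L] == 0L
  expect_gte(mean(st$failures == truth_fail), 0.99)
})

test_that("alignment modes behave as documented", {
  ss <- one_quantum_trials(rep(0.8, 3))
  for (mode in c("ap_peak", "half_rise")) {
    avg <- align_and_average(ss, mode)
    # average of identical traces preserves the trace (peak amplitude)
    expect_equal(min(avg$trace), min(ss$sweeps[, 1L]), tolerance = 0.5)
    expect_identical(length(avg$trace), length(avg$t))
  }
  # jitter-cancelling property of half-rise alignment
  ss2 <- one_quantum_trials(c(0.7, 0.9))
  avg_hr <- align_and_average(ss2, "half_rise")
  single <- align_and_average(one_quantum_trials(0.8), "half_rise")
  width_of <- function(a) {
    y <- -a$trace
    pk <- max(y)
    rng <- range(a$t[y >= pk / 2])
    diff(rng)
  }
  expect_equal(width_of(avg_hr), width_of(single), tolerance = 0.01)
  # ap_peak alignment preserves the ensemble mean latency: the averaged
  # peak sits at mean release latency + kernel peak time after the AP
  avg_ap <- align_and_average(ss2, "ap_peak")
  pk_t <- avg_ap$t[which.min(avg_ap$trace)]
  expect_equal(pk_t, 0.8 + waveform_peak_time(std_waveform()),
               tolerance = 0.1)
  expect_error(align_and_average(
    one_quantum_trials(c(NA, NA), noise = noise_model(1, 10), seed = 3),
    "half_rise"), "failure")
})

test_that("train amplitudes use the preceding baseline and normalize by IPSC1", {
  q <- std_waveform("inward")
  ap <- seq(10, 190, by = 20) # 50 Hz: no overlap at tau_decay 5 ms
  rel <- list(data.frame(time = ap + 1, amp_factor = rep(1, length(ap))))
  ss <- render_sweeps(manual_truth(rel, ap_times = ap), q, NULL,
                      dt = 0.02, duration = 250)
  tr <- measure_train(ss)
  expect_equal(tr$normalized, rep(1, 10), tolerance = 0.02)
  # geometric depletion: IPSC_n = (1 - Pr)^(n-1), Pr = 0.2
  gaf <- 0.8^(seq_along(ap) - 1L)
  rel2 <- list(data.frame(time = ap + 1, amp_factor = gaf))
  ss2 <- render_sweeps(manual_truth(rel2, ap_times = ap), q, NULL,
                       dt = 0.02, duration = 250)
  tr2 <- measure_train(ss2)
  expect_equal(tr2$normalized, gaf, tolerance = 0.03)
  expect_error(measure_train(sweep_set(matrix(rnorm(1000), ncol = 1),
                                       dt = 0.02, ap_times = c(1, 2.5))),
               "500 Hz")
})

test_that("steady-state depression at the Syt2-rescue parameters is 0.4-0.7", {
  m <- release_model_preset("syt2_rescue")
  ap <- seq(0, 490, by = 10)
  truth <- simulate_pool_train(m, ap, n_sweeps = 10, seed = 31)
  truth <- draw_release_times(truth, seed = 32)
  ss <- render_sweeps(truth, std_waveform("inward"), noise_model(2, 10),
                      dt = 0.05, duration = 560, seed = 33)
  tr <- measure_train(ss)
  expect_gt(tr$normalized[50L], 0.4)
  expect_lt(tr$normalized[50L], 0.7)
})

test_that("decay fitting recovers mono- and dominant biexponential constants", {
  tt <- seq(0, 60, by = 0.02)
  pure <- 80 * exp(-tt / 5)
  fit <- decay_fit(pure, 0.02)
  expect_equal(fit$tau, 5, tolerance = 0.002)
  k <- make_quantal_waveform(std_waveform("outward"), 0.02, 60)
  fit2 <- decay_fit(k, 0.02, offset_ms = 1)
  expect_equal(fit2$tau, 5, tolerance = 0.05 * 5)
  expect_error(decay_fit(rep(1, 1000), 0.02), "fit failed")
  expect_error(decay_fit(c(numeric(100), seq(0, 1, length.out = 900)), 0.02),
               "fit failed")
})

test_that("conductance arithmetic matches the driving-force relation", {
  expect_equal(conductance_from_current(-138, -60, 0), 2.3)
  expect_equal(conductance_from_current(0, -60, 0), 0)
  g1 <- conductance_from_current(-100, -60, 0)
  g2 <- conductance_from_current(-100, -120, 0)
  expect_equal(g1, 2 * g2)
  expect_error(conductance_from_current(-100, -60, -60), "reversal")
})

test_that("E-I delay is recovered peak to peak", {
  dt <- 0.02
  t <- seq(0, 80, by = dt)
  transient <- function(onset, tau_r = 0.5, tau_d = 4) {
    tt <- pmax(t - onset, 0)
    a <- (1 - exp(-tt / tau_r)) * exp(-tt / tau_d)
    a[t < onset] <- 0
    a
  }
  epsc <- -120 * transient(10)
  for (true_delay in c(4.9, 20.8)) {
    ipsc <- 300 * transient(10 + true_delay)
    d <- ei_delay(epsc, ipsc, dt)
    expect_true(d$defined)
    expect_equal(d$delay, true_delay, tolerance = dt)
  }
  d0 <- ei_delay(epsc, -epsc, dt)
  expect_equal(d0$delay, 0, tolerance = 1e-9)
  # absent IPSC: flagged undefined
  set.seed(12)
  d_na <- ei_delay(epsc, rnorm(length(t), sd = 2), dt)
  expect_false(d_na$defined)
  expect_true(is.na(d_na$delay))
})

test_that("rank-sum and Kruskal-Wallis wrappers match exact conventions", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1)
  # disjoint support, n = 5/5: exact p = 2/choose(10, 5)
  p <- compare_groups(1:5, 6:10)
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-12)
  # enumeration oracle: count labelings at least as extreme
  vals <- c(1:5, 6:10)
  obs <- sum(rank(vals)[1:5])
  combos <- utils::combn(10, 5)
  w <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
  mu <- mean(w)
  p_oracle <- mean(abs(w - mu) >= abs(obs - mu))
  expect_equal(p, p_oracle, tolerance = 1e-12)
  expect_error(compare_groups(1, 2:4), "n >= 2")
  expect_gt(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))), 0.9)
  expect_lt(kruskal_wallis(list(1:5, 11:15, 21:25)), 0.01)
})
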