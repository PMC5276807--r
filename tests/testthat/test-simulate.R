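ap10 <- seq(0, 180, by = 20)

test_that("degenerate release regimes behave as required", {
  m_full <- release_model(pool_size = 50, release_prob = 1, replenish_rate = 0)
  tr <- simulate_pool_train(m_full, ap10, n_sweeps = 3, seed = 1)
  expect_true(all(tr$counts[, 1L] == 50L))
  expect_true(all(tr$counts[, -1L] == 0L))
  expect_true(all(tr$pool_before[, 1L] == 50L))
  m_silent <- release_model(pool_size = 50, release_prob = 0)
  expect_true(all(simulate_pool_train(m_silent, ap10, 3, seed = 1)$counts == 0L))
  expect_error(simulate_pool_train(m_full, numeric(0), 1), "non-empty")
  expect_error(simulate_pool_train(m_full, c(10, 5), 1), "increasing")
})

test_that("released counts match binomial moments and pool bounds", {
  m <- release_model(pool_size = 44, release_prob = 0.2, replenish_rate = 0.3)
  n_sweeps <- 10000L
  tr <- simulate_pool_train(m, seq(0, 90, 10), n_sweeps = n_sweeps, seed = 11)
  expect_true(all(tr$pool_before >= 0L & tr$pool_before <= 44L))
  # per-AP mean and variance vs N_eff * Pr (N_eff = mean pool before the AP)
  for (i in c(1L, 3L, 8L)) {
    n_eff <- mean(tr$pool_before[, i])
    mu <- n_eff * 0.2
    # conditional variance + variance of the conditional mean
    v <- mu * 0.8 + stats::var(tr$pool_before[, i]) * 0.2^2
    se_mu <- sqrt(v / n_sweeps)
    expect_lt(abs(mean(tr$counts[, i]) - mu), 3 * se_mu)
    se_v <- v * sqrt(2 / (n_sweeps - 1)) * 2 # generous SE for a variance
    expect_lt(abs(stats::var(tr$counts[, i]) - v), 3 * se_v + 0.05 * v)
  }
  expect_equal(mean(tr$counts[, 1L]), 8.8, tolerance = 0.02)
})

test_that("identical seeds give bit-identical ground truth", {
  m <- release_model_preset("syt2_rescue")
  a <- draw_release_times(simulate_pool_train(m, ap10, 5, seed = 99), seed = 7)
  b <- draw_release_times(simulate_pool_train(m, ap10, 5, seed = 99), seed = 7)
  expect_identical(a, b)
  c_ <- simulate_pool_train(m, ap10, 5, seed = 100)
  expect_false(identical(a$counts, c_$counts))
  # extending n_sweeps must not perturb earlier sweeps
  wide <- simulate_pool_train(m, ap10, 8, seed = 99)
  expect_identical(wide$counts[1:5, ], a$counts)
})

test_that("release-time draws follow the requested TCR", {
  m <- release_model(pool_size = 400, release_prob = 0.5, replenish_rate = 0,
                     tcr_latency = 1.17, tcr_half_duration = 0.78,
                     quantal_cv = 0.3)
  tr <- draw_release_times(simulate_pool_train(m, 0, 500, seed = 3), seed = 4)
  lat <- unlist(lapply(tr$release, function(r) r$time))
  expect_gt(length(lat), 5e4)
  expect_equal(stats::sd(lat), 0.78 / 2.3548, tolerance = 0.02)
  dens <- stats::density(lat, bw = 0.02)
  expect_equal(dens$x[which.max(dens$y)], 1.17, tolerance = 0.05)
  # per-quantum amplitude factors: mean 1, CV as configured
  af <- unlist(lapply(tr$release, function(r) r$amp_factor))
  expect_equal(mean(af), 1, tolerance = 0.01)
  expect_equal(stats::sd(af) / mean(af), 0.3, tolerance = 0.02)
})

test_that("asynchronous release obeys its rates and tags", {
  m_none <- release_model(pool_size = 10, release_prob = 0.5,
                          async_rate_train = 0, async_rate_post = 0)
  tr <- draw_release_times(simulate_pool_train(m_none, ap10, 20, seed = 5),
                           seed = 6)
  tags <- unlist(lapply(tr$release, function(r) r$tag))
  expect_false(any(tags == "asynchronous"))
  m_async <- release_model(pool_size = 0, release_prob = 0,
                           async_rate_train = 0.05, async_rate_post = 0.2,
                           async_post_tau = 30)
  tr <- draw_release_times(simulate_pool_train(m_async, ap10, 400, seed = 5),
                           seed = 6)
  n_async <- mean(vapply(tr$release, nrow, 1L))
  # expected: rate * span (200 ms) + post mass rate0 * tau
  expect_equal(n_async, 0.05 * 200 + 0.2 * 30, tolerance = 0.05)
  expect_error(release_model(tcr_family = "cauchy"), "arg")
})

test_that("rendering is an exact superposition of shifted kernels", {
  q <- std_waveform("outward")
  dt <- 0.02
  k <- make_quantal_waveform(q, dt, 50)
  # one quantum on-grid at 10 ms: trace equals the delayed kernel
  tr1 <- render_sweeps(manual_truth(list(data.frame(time = 10))), q,
                       noise = NULL, dt = dt, duration = 80)
  i0 <- round(10 / dt)
  expect_equal(tr1$sweeps[(i0 + 1):(i0 + length(k)), 1L], k, tolerance = 1e-9)
  expect_true(all(abs(tr1$sweeps[1:i0, 1L]) < 1e-9))
  # two coincident quanta: exact doubling
  tr2 <- render_sweeps(manual_truth(list(data.frame(time = c(10, 10)))), q,
                       noise = NULL, dt = dt, duration = 80)
  expect_equal(max(tr2$sweeps), 2 * max(tr1$sweeps), tolerance = 1e-3)
  # off-grid placement: linear interpolation bound (documented error bound)
  tr3 <- render_sweeps(manual_truth(list(data.frame(time = 10.01))), q,
                       noise = NULL, dt = dt, duration = 80)
  shift_ref <- 0.5 * (c(0, k[-length(k)]) + k)
  expect_equal(tr3$sweeps[(i0 + 1):(i0 + length(k)), 1L], shift_ref,
               tolerance = 1e-9)
})

test_that("noiseless rendered charge is conserved", {
  q <- std_waveform("outward")
  dt <- 0.02
  k <- make_quantal_waveform(q, dt, 50)
  kernel_charge <- sum(k) * dt
  af <- c(0.8, 1.1, 1.3, 0.9, 1.05)
  tr <- render_sweeps(manual_truth(list(
    data.frame(time = c(20, 60, 100, 140, 180), amp_factor = af))), q,
    noise = NULL, dt = dt, duration = 300)
  expect_equal(sum(tr$sweeps) * dt, kernel_charge * sum(af),
               tolerance = 0.005 * kernel_charge * sum(af))
})

test_that("mini simulation is Poisson in count and time", {
  q <- std_waveform("inward")
  expect_identical(
    length(simulate_mini_sweep(0, 1, q, NULL, seed = 1)$event_times), 0L)
  counts <- vapply(1:200, function(s) {
    with(simulate_mini_sweep(20, 1, q, NULL, dt = 0.5, seed = s),
         length(event_times))
  }, 1)
  expect_equal(mean(counts), 20, tolerance = 0.1)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.35)
  # inter-event intervals exponential (KS at alpha = 0.01 across seeds)
  pvals <- vapply(1:20, function(s) {
    ev <- simulate_mini_sweep(20, 10, q, NULL, dt = 0.5, seed = s)$event_times
    stats::ks.test(diff(ev), stats::pexp, rate = 20 / 1000)$p.value
  }, 1)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("recovery protocol follows the linear-saturating pool ODE", {
  # deterministic regime: Pr = 1 empties the pool at the first test AP
  m <- release_model(pool_size = 40, release_prob = 1, replenish_rate = 0.01,
                     quantal_cv = 0)
  ints <- c(100, 500, 1000, 2000, 4000, 8000)
  counts <- sapply(1:60, function(s) {
    tr <- simulate_recovery_protocol(m, ints, n_train = 10, freq_hz = 100,
                                     seed = s)
    tr$counts[, ncol(tr$counts)]
  })
  got <- rowMeans(counts)
  # closed form: pool at train end is 0 (Pr = 1), recovers at r per ms, cap N
  expected <- pmin(0 + 0.01 * ints, 40)
  expect_equal(got, expected, tolerance = 0.06 * max(expected))
  # very long interval: full recovery to IPSC1
  expect_equal(got[length(ints)], 40, tolerance = 1)
  expect_error(simulate_recovery_protocol(m, c(-1, 10)), "> 0")
})

test_that("feedforward sweep obeys driving-force arithmetic", {
  exc <- list(peak = 2.3, tau_rise = 0.5, tau_decay = 3, onset = 10)
  inh <- list(peak = 5, tau_rise = 1, tau_decay = 8, onset = 10)
  # at V = E_inh only the EPSC is visible; peak = g * (V - E_exc)
  ss <- render_ffi_sweep(exc, inh, delay = 2, holding = -85,
                         reversal_exc = 0, reversal_inh = -85)
  expect_equal(min(ss$sweeps), 2.3 * (-85 - 0), tolerance = 0.01 * 195.5)
  # at V = E_exc only the IPSC remains (outward)
  ss2 <- render_ffi_sweep(exc, inh, delay = 2, holding = 0,
                          reversal_exc = 0, reversal_inh = -85)
  expect_equal(max(ss2$sweeps), 5 * (0 - -85), tolerance = 0.01 * 425)
  expect_gte(min(ss2$sweeps), -1e-9)
  # the printed-value arithmetic: 2.3 nS at -60 mV vs E = 0 gives -138 pA
  ss3 <- render_ffi_sweep(exc, inh = NULL, holding = -60, reversal_exc = 0)
  expect_equal(min(ss3$sweeps), -138, tolerance = 0.2)
})

test_that("sweep-set invariants are enforced", {
  expect_error(sweep_set(matrix(0, 10, 2), dt = -1), "dt")
  expect_error(sweep_set(matrix(0, 10, 2), dt = 1,
                         ap_times = list(c(5, 3), c(1, 2))), "increasing")
  expect_error(sweep_set(matrix(0, 10, 2), dt = 1, ap_times = list(1)),
               "one entry per sweep")
  ss <- sweep_set(matrix(0, 10, 2), dt = 0.5, ap_times = c(1, 2))
  expect_identical(ss$ap_times, list(c(1, 2), c(1, 2)))
  expect_equal(sweep_times(ss), seq(0, 4.5, 0.5))
})
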