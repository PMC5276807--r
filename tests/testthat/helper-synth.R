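# Shared fixtures, built in code at test time.

# Standard 100 pA / 0.3 ms / 5 ms quantal waveform used throughout.
std_waveform <- function(polarity = "outward") {
  quantal_waveform(amplitude = 100, tau_rise = 0.3, tau_decay = 5,
                   polarity = polarity)
}

# Noiseless ground truth with hand-set release times/amplitude factors:
# a list of data.frames (one per sweep) is wrapped into the class the
# renderer expects.
manual_truth <- function(release, ap_times = 0) {
  n <- length(release)
  structure(list(
    counts = matrix(vapply(release, nrow, 1L), n, 1L),
    pool_before = matrix(0L, n, 1L),
    ap_times = ap_times, model = NULL, seed = NULL,
    release = lapply(release, function(r) {
      r$tag <- r$tag %||% rep("synchronous", nrow(r))
      r$ap_index <- r$ap_index %||% rep(1L, nrow(r))
      r$amp_factor <- r$amp_factor %||% rep(1, nrow(r))
      r[, c("time", "tag", "ap_index", "amp_factor")]
    })), class = "release_ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One simulated pool-train "experiment" analysed end to end; returns the
# absolute pool estimate (back-extrapolation + fluctuation analysis).
pool_experiment <- function(model, seed, n_sweeps = 10, n_ap = 50,
                            isi = 10, q_pa = 100) {
  ap <- (seq_len(n_ap) - 1L) * isi
  truth <- simulate_pool_train(model, ap, n_sweeps = n_sweeps, seed = seed)
  truth <- draw_release_times(truth, seed = seed + 50000L)
  amp <- amplitude_matrix(truth, quantal_amplitude = q_pa)
  tr <- structure(list(amplitudes = colMeans(amp),
                       normalized = colMeans(amp) / mean(amp[, 1L]),
                       ap_times = ap, isi = isi),
                  class = "train_amplitudes")
  pool <- cumulative_pool_analysis(tr)
  fl <- fluctuation_analysis(amp)
  if (fl$valid) pool <- to_absolute(pool, quantal_size = fl$quantal_size)
  list(pool = pool, fluctuation = fl, amp = amp)
}
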