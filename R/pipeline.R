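#' Default pipeline configuration
#'
#' Returns the full declarative configuration of the simulation/analysis
#' pipeline with every parameter at its default.  Protocol constants follow
#' the standard paired-recording design: deconvolution trains of 10 APs at
#' 50 Hz, pool trains of 50 APs at 100 Hz, recovery intervals from 0.1 to
#' 12 s, release windows 0-5 / 15-20 / >20 ms, last 10 cumulative points in
#' the pool regression, and a 2 kHz display filter for release rates.
#' Every entry can be overridden via `run_pipeline(config = ...)` or a JSON
#' config file with the same structure.
#'
#' @param seed Global integer seed; per-stage, per-sweep substreams are
#'   derived from it so outputs are bit-reproducible.
#' @return A nested list (class `synquant_config`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = c("simulate", "detect", "unitary", "deconvolve", "pool",
               "recovery"),
    model = list(preset = "syt2_rescue"),
    waveform = list(amplitude = 100, tau_rise = 0.3, tau_decay = 5,
                    polarity = "inward"),
    noise = list(sd = 2, bandwidth = 10),
    dt_ms = 0.02,
    unitary = list(n_sweeps = 50, window_ms = 20, failure_k = 3),
    deconvolve = list(n_ap = 10, freq_hz = 50, cutoff_khz = 2),
    pool = list(n_ap = 50, freq_hz = 100, n_sweeps = 10, last_k = 10),
    recovery = list(intervals_s = c(0.1, 0.3, 1, 2, 4, 8, 12)),
    minis = list(rate_hz = 3.75, duration_s = 100, dt_ms = 0.05,
                 threshold = 4, refractory_ms = 1),
    out_dir = NULL), class = "synquant_config")
}

# Recursively overlay user values onto the defaults.
merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

# Validate a merged config; unknown top-level keys are a configuration
# error listing the offending names.
validate_config <- function(config) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop_invalid("unknown configuration keys: %s", paste(extra, collapse = ", "))
  bad <- setdiff(config$stages,
                 c("simulate", "detect", "unitary", "deconvolve", "pool",
                   "recovery"))
  if (length(bad))
    stop_invalid("unknown stages: %s", paste(bad, collapse = ", "))
  invisible(config)
}

config_model <- function(config) {
  mc <- config$model
  if (!is.null(mc$preset)) {
    m <- release_model_preset(mc$preset)
    extra <- mc[setdiff(names(mc), "preset")]
    if (length(extra)) {
      args <- unclass(m)[setdiff(names(unclass(m)), names(extra))]
      m <- do.call(release_model, c(args, extra))
    }
    m
  } else {
    do.call(release_model, mc)
  }
}

#' Run the end-to-end simulation and analysis pipeline
#'
#' Executes the selected stages in dependency order: `simulate` (ground
#' truth + rendered sweeps), `detect` (miniature-event template matching),
#' `unitary` (single-AP statistics), `deconvolve` (release-rate and window
#' quantification on the 10-AP 50-Hz train), `pool` (cumulative /
#' fluctuation analysis on the 50-AP 100-Hz train), and `recovery`
#' (post-train refilling kinetics).  Results are returned as a structured
#' report and, when `out_dir` is set, persisted per stage as CSV/JSON with
#' a provenance block.
#'
#' @param config A config list (see [default_config()]), a path to a JSON
#'   file with the same structure, or `NULL` for all defaults.
#' @param seed Optional override of the config seed.
#' @param out_dir Optional override of the output directory.
#' @return A `run_report` list: `config`, `config_hash`, `seed`, `results`
#'   (one entry per executed stage), and `timing_s`.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- merge_config(default_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  validate_config(cfg)
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  hash <- fnv1a(as.character(cfg_json))
  model <- config_model(cfg)
  wf <- do.call(quantal_waveform, cfg$waveform)
  noise <- do.call(noise_model, cfg$noise)
  results <- list()
  timing <- numeric(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      message(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
      structure(list(error = conditionMessage(e)), class = "stage_failure")
    })
    timing[[stage]] <<- proc.time()[["elapsed"]] - t0
    results[[stage]] <<- value
    message(sprintf("[synquant] stage %-10s %6.2f s", stage, timing[[stage]]))
    value
  }
  run <- cfg$stages
  sim <- NULL
  if ("simulate" %in% run) {
    sim <- tick("simulate", {
      ap <- (seq_len(cfg$deconvolve$n_ap) - 1L) * 1000 / cfg$deconvolve$freq_hz
      truth <- simulate_pool_train(model, ap, n_sweeps = cfg$unitary$n_sweeps,
                                   seed = derive_seed(cfg$seed, 1L))
      truth <- draw_release_times(truth, seed = derive_seed(cfg$seed, 2L))
      sweeps <- render_sweeps(truth, wf, noise, dt = cfg$dt_ms,
                              seed = derive_seed(cfg$seed, 3L),
                              condition = "2 mM Ca")
      list(truth = truth, sweeps = sweeps)
    })
  }
  if ("detect" %in% run) {
    tick("detect", {
      mini <- simulate_mini_sweep(cfg$minis$rate_hz, cfg$minis$duration_s, wf,
                                  noise, dt = cfg$minis$dt_ms,
                                  seed = derive_seed(cfg$seed, 4L))
      cfg_tm <- template_match_config(wf, cfg$minis$threshold,
                                      cfg$minis$refractory_ms,
                                      direction = if (wf$polarity == "inward")
                                        "negative" else "positive",
                                      dt = cfg$minis$dt_ms)
      ev <- template_match(mini$sweeps, cfg_tm)
      list(events = ev, stats = event_statistics(ev),
           true_frequency_hz = length(mini$event_times) / cfg$minis$duration_s)
    })
  }
  if ("unitary" %in% run) {
    tick("unitary", {
      ap1 <- 10
      truth1 <- simulate_pool_train(model, ap1, n_sweeps = cfg$unitary$n_sweeps,
                                    seed = derive_seed(cfg$seed, 5L))
      truth1 <- draw_release_times(truth1, seed = derive_seed(cfg$seed, 6L))
      sw <- render_sweeps(truth1, wf, noise, dt = cfg$dt_ms,
                          duration = ap1 + 60,
                          seed = derive_seed(cfg$seed, 7L))
      measure_unitary(sw, window = cfg$unitary$window_ms,
                      failure_k = cfg$unitary$failure_k)
    })
  }
  if ("deconvolve" %in% run &&
      (is.null(sim) || inherits(sim, "stage_failure"))) {
    results$deconvolve <- structure(
      list(error = "skipped: requires the simulate stage"),
      class = "stage_failure")
  } else if ("deconvolve" %in% run) {
    tick("deconvolve", {
      avg <- rowMeans(sim$sweeps$sweeps)
      rr <- fourier_deconvolve(avg, wf, dt = cfg$dt_ms,
                               cutoff_khz = cfg$deconvolve$cutoff_khz,
                               ap_times = sim$truth$ap_times)
      rr$rate <- rr$rate * sign(sum(rr$rate)) # polarity-neutral quanta
      win <- quantify_windows(rr)
      list(rate = rr, windows = win,
           true_total = mean(rowSums(sim$truth$counts)))
    })
  }
  if ("pool" %in% run) {
    tick("pool", {
      ap <- (seq_len(cfg$pool$n_ap) - 1L) * 1000 / cfg$pool$freq_hz
      truth <- simulate_pool_train(model, ap, n_sweeps = cfg$pool$n_sweeps,
                                   seed = derive_seed(cfg$seed, 8L))
      truth <- draw_release_times(truth, seed = derive_seed(cfg$seed, 9L))
      amp_mat <- amplitude_matrix(truth, wf$amplitude)
      tr <- structure(list(amplitudes = colMeans(amp_mat),
                           normalized = colMeans(amp_mat) / mean(amp_mat[, 1L]),
                           ap_times = ap, isi = 1000 / cfg$pool$freq_hz),
                      class = "train_amplitudes")
      pool <- cumulative_pool_analysis(tr, last_k = cfg$pool$last_k)
      fl <- fluctuation_analysis(amp_mat)
      if (fl$valid) pool <- to_absolute(pool, quantal_size = fl$quantal_size)
      list(pool = pool, fluctuation = fl,
           true_pool = model$pool_size, true_pr = model$release_prob)
    })
  }
  if ("recovery" %in% run) {
    tick("recovery", {
      ints_ms <- cfg$recovery$intervals_s * 1000
      n_rep <- 10L
      amps <- sapply(seq_len(n_rep), function(r) {
        truth <- simulate_recovery_protocol(
          model, ints_ms, n_train = cfg$pool$n_ap, freq_hz = cfg$pool$freq_hz,
          seed = derive_seed(cfg$seed, 100L + r))
        n_ap <- ncol(truth$counts)
        truth$counts[, n_ap] / mean(truth$counts[, 1L])
      })
      rec <- recovery_fit(rowMeans(amps), cfg$recovery$intervals_s)
      list(recovery = rec, intervals_s = cfg$recovery$intervals_s,
           amplitudes = rowMeans(amps))
    })
  }
  report <- structure(list(config = cfg, config_hash = hash, seed = cfg$seed,
                           package_version = as.character(
                             utils::packageVersion("synquant")),
                           results = results, timing_s = timing),
                      class = "run_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, config %s, stages: %s\n", x$seed,
              x$config_hash, paste(names(x$results), collapse = ", ")))
  invisible(x)
}

# Persist a run report: one JSON summary plus per-stage CSV tables.  Every
# numeric column name carries its unit suffix.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = report$config_hash, seed = report$seed,
               package_version = report$package_version)
  summarize <- function(stage, r) {
    if (inherits(r, "stage_failure")) return(list(error = r$error))
    switch(stage,
      detect = list(frequency_hz = r$stats$frequency_hz,
                    true_frequency_hz = r$true_frequency_hz,
                    mean_amplitude_pa = r$stats$mean_amplitude_pa,
                    n_events = r$stats$n_events),
      unitary = list(mean_amplitude_pa = r$mean_amplitude,
                     failure_fraction = r$failure_fraction,
                     cv = r$cv, skewness = r$skewness,
                     latency_mean_ms = r$latency_mean,
                     latency_sd_ms = r$latency_sd,
                     decay_tau_ms = r$decay_tau),
      deconvolve = list(total_quanta = r$windows$total,
                        sync_quanta = r$windows$sync,
                        async_train_quanta = r$windows$async_train,
                        async_post_quanta = r$windows$async_post,
                        true_total_quanta = r$true_total),
      pool = list(rrp_norm = r$pool$rrp_norm, pr = r$pool$pr,
                  rrp_abs_vesicles = r$pool$rrp_abs,
                  refill_rate_quanta_per_ms = r$pool$refill_rate_abs,
                  quantal_size_pa = r$fluctuation$quantal_size,
                  true_pool_vesicles = r$true_pool, true_pr = r$true_pr),
      recovery = list(tau_s = r$recovery$tau,
                      asymptote = r$recovery$asymptote,
                      depressed = r$recovery$depressed),
      simulate = list(n_sweeps = ncol(r$sweeps$sweeps),
                      mean_quanta_per_sweep = mean(rowSums(r$truth$counts))))
  }
  out <- list(provenance = prov,
              results = mapply(summarize, names(report$results),
                               report$results, SIMPLIFY = FALSE))
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$results$detect) &&
      !inherits(report$results$detect, "stage_failure")) {
    write_event_table(report$results$detect$events,
                      file.path(out_dir, "events.csv"),
                      file.path(out_dir, "iei_cumulative.csv"))
  }
  if (!is.null(report$results$simulate) &&
      !inherits(report$results$simulate, "stage_failure")) {
    write_sweepset(report$results$simulate$sweeps,
                   file.path(out_dir, "sweeps"))
  }
  invisible(out_dir)
}

#' Serialize ground-truth release times as JSON lines
#'
#' One JSON object per sweep with tagged release times, released counts and
#' pool occupancies, suitable for `jsonlite::stream_in()`.
#'
#' @param truth A `release_ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(nrow(truth$counts))) {
    rec <- list(sweep = s, counts = truth$counts[s, ],
                pool_before = truth$pool_before[s, ])
    if (!is.null(truth$release)) {
      r <- truth$release[[s]]
      rec$release <- list(time_ms = r$time, tag = r$tag,
                          ap_index = r$ap_index, amp_factor = r$amp_factor)
    }
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, na = "null")), con)
  }
  invisible(path)
}
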