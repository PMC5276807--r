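#' Sweep set: a group of current sweeps on a common time base
#'
#' The universal pipeline input: an ordered collection of voltage-clamp
#' current traces (pA) sharing one sampling interval, together with the
#' presynaptic AP peak times of each sweep and recording metadata.
#'
#' @param sweeps Numeric matrix, one column per sweep (samples x sweeps), or
#'   a single numeric vector.
#' @param dt Sampling interval in ms.
#' @param ap_times List of numeric vectors (one per sweep) of AP peak times
#'   in ms, each strictly increasing and within the trace duration; or one
#'   vector recycled for every sweep.
#' @param condition Free-text label (e.g. external Ca2+ in mM).
#' @param holding_potential Holding potential in mV.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, dt, ap_times = list(), condition = "",
                      holding_potential = -70) {
  if (is.numeric(sweeps) && is.null(dim(sweeps)))
    sweeps <- matrix(sweeps, ncol = 1L)
  sweeps <- as.matrix(sweeps)
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be positive")
  n_sweeps <- ncol(sweeps)
  dur <- nrow(sweeps) * dt
  if (is.numeric(ap_times)) ap_times <- rep(list(ap_times), n_sweeps)
  if (length(ap_times) == 0L) ap_times <- rep(list(numeric(0)), n_sweeps)
  if (length(ap_times) != n_sweeps)
    stop_invalid("ap_times must have one entry per sweep (%d != %d)",
                 length(ap_times), n_sweeps)
  for (ap in ap_times) {
    if (length(ap) && (is.unsorted(ap, strictly = TRUE) ||
                       any(ap < 0) || any(ap >= dur)))
      stop_invalid("ap_times must be strictly increasing within [0, %g) ms", dur)
  }
  structure(list(sweeps = sweeps, dt = dt, ap_times = ap_times,
                 condition = condition,
                 holding_potential = holding_potential),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %d sweep(s) x %d samples, dt %.4g ms (%.4g ms), %d AP(s)/sweep%s\n",
    ncol(x$sweeps), nrow(x$sweeps), x$dt, nrow(x$sweeps) * x$dt,
    length(x$ap_times[[1L]]),
    if (nzchar(x$condition)) paste0(", ", x$condition) else ""))
  invisible(x)
}

#' Time axis of a sweep set
#' @param x A [sweep_set()].
#' @return Numeric vector of sample times in ms starting at 0.
#' @export
sweep_times <- function(x) (seq_len(nrow(x$sweeps)) - 1L) * x$dt

#' Write / read a sweep set as a text container
#'
#' The container is a directory holding three plain-text members mirroring
#' the groups of an HDF5-style layout: `sweeps.csv` (column `time_ms`
#' followed by one column per sweep, in pA), `ap_times.json`, and
#' `meta.json` (dt, condition, holding potential, format version).
#' `write_sweepset_csv()` / `read_sweepset_csv()` provide a single-file
#' fallback with the metadata in `#`-prefixed header lines.
#'
#' @param x A [sweep_set()].
#' @param path Directory (container) or file (CSV fallback) path.
#' @return `read_sweepset()` returns a [sweep_set()]; the writers return
#'   `path` invisibly.
#' @export
write_sweepset <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  # %.17g formatting makes the text round trip bit-exact for doubles
  m <- cbind(sweep_times(x), x$sweeps)
  colnames(m) <- c("time_ms", paste0("sweep_", seq_len(ncol(x$sweeps)), "_pA"))
  fm <- apply(m, 2L, function(col) sprintf("%.17g", col))
  utils::write.table(rbind(colnames(m), fm), file.path(path, "sweeps.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(x$ap_times, file.path(path, "ap_times.json"),
                       digits = NA)
  jsonlite::write_json(list(dt_ms = x$dt, condition = x$condition,
                            holding_potential_mV = x$holding_potential,
                            format = "synquant-sweepset-1"),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweepset
#' @export
read_sweepset <- function(path) {
  if (!dir.exists(path)) {
    if (file.exists(path)) return(read_sweepset_csv(path))
    stop_invalid("no sweep-set container at '%s'", path)
  }
  for (f in c("sweeps.csv", "ap_times.json", "meta.json"))
    if (!file.exists(file.path(path, f)))
      stop_invalid("malformed container: missing member '%s'", f)
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (is.null(meta$dt_ms)) stop_invalid("malformed container: meta lacks dt_ms")
  df <- utils::read.csv(file.path(path, "sweeps.csv"))
  ap <- jsonlite::read_json(file.path(path, "ap_times.json"),
                            simplifyVector = FALSE)
  ap <- lapply(ap, function(a) as.numeric(unlist(a)))
  sweep_set(as.matrix(df[, -1L, drop = FALSE]), dt = meta$dt_ms,
            ap_times = ap, condition = meta$condition %||% "",
            holding_potential = meta$holding_potential_mV %||% -70)
}

#' @rdname write_sweepset
#' @export
write_sweepset_csv <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dt_ms=%.17g", x$dt),
    sprintf("# condition=%s", x$condition),
    sprintf("# holding_potential_mV=%.17g", x$holding_potential),
    sprintf("# ap_times_ms=%s",
            paste(vapply(x$ap_times, function(a) paste(a, collapse = ","),
                         ""), collapse = ";"))), con)
  m <- x$sweeps
  colnames(m) <- paste0("sweep_", seq_len(ncol(x$sweeps)), "_pA")
  fm <- apply(m, 2L, function(col) sprintf("%.17g", col))
  utils::write.table(rbind(colnames(m), fm), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweepset
#' @export
read_sweepset_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1L])
  }
  dt <- get("dt_ms")
  if (is.null(dt)) stop_invalid("CSV sweep set lacks '# dt_ms=' header")
  ap_raw <- get("ap_times_ms") %||% ""
  ap <- lapply(strsplit(ap_raw, ";", fixed = TRUE)[[1L]], function(s) {
    if (!nzchar(s)) numeric(0) else as.numeric(strsplit(s, ",")[[1L]])
  })
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  sweep_set(as.matrix(df), dt = as.numeric(dt), ap_times = ap,
            condition = get("condition") %||% "",
            holding_potential = as.numeric(get("holding_potential_mV") %||% "-70"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
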