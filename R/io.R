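#' Trace set: uniformly sampled runs of one probe
#'
#' @param traces numeric matrix, runs x time points (volts for voltage
#'   probes), or a vector for a single run.
#' @param dt sampling step (s).
#' @param probe probe label.
#' @param t0 time of the first sample (s).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, dt, probe = "V", t0 = 0) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  stopifnot(is.matrix(traces), dt > 0)
  structure(list(traces = traces, dt = dt, probe = probe, t0 = t0),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> probe '%s': %d runs x %d samples at dt = %g s\n",
              x$probe, nrow(x$traces), ncol(x$traces), x$dt))
  invisible(x)
}

#' Write / read a trace set as CSV
#'
#' Full-double-precision CSV with a header line declaring the sampling
#' step and probe; `read_traces` verifies that the time column matches the
#' declared step and errors on mismatch.
#'
#' @param ts a [trace_set()].
#' @param path file path.
#' @return `write_traces`: `path` invisibly; `read_traces`: a
#'   [trace_set()].
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tetsim-traces dt=%.17g t0=%.17g probe=%s runs=%d",
                     ts$dt, ts$t0, ts$probe, nrow(ts$traces)), con)
  n_run <- nrow(ts$traces)
  hdr <- paste(c("time_s", sprintf("run_%04d", seq_len(n_run))),
               collapse = ",")
  writeLines(hdr, con)
  times <- ts$t0 + (seq_len(ncol(ts$traces)) - 1) * ts$dt
  body <- cbind(times, t(ts$traces))
  utils::write.table(format(body, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!startsWith(hdr[1], "# tetsim-traces")) {
    stop("malformed trace file: missing '# tetsim-traces' header with the ",
         "declared sampling step (columns found: ",
         paste(strsplit(hdr[1], ",")[[1]], collapse = " "), ")",
         call. = FALSE)
  }
  kv <- strsplit(sub("^# tetsim-traces ", "", hdr[1]), " ")[[1]]
  fields <- do.call(rbind, strsplit(kv, "="))
  get_field <- function(k) fields[fields[, 1] == k, 2]
  dt <- as.numeric(get_field("dt"))
  t0 <- as.numeric(get_field("t0"))
  probe <- get_field("probe")
  tab <- utils::read.csv(path, comment.char = "#", header = TRUE)
  times <- tab[[1]]
  if (length(times) > 1) {
    steps <- diff(times)
    if (max(abs(steps - dt)) > 1e-9 * max(dt, 1e-300)) {
      stop(sprintf("trace file declares dt = %g but time column steps by %g",
                   dt, stats::median(steps)), call. = FALSE)
    }
  }
  trace_set(t(as.matrix(tab[, -1, drop = FALSE])), dt = dt, probe = probe,
            t0 = t0)
}

#' Dump the SSA diagnostic event log as CSV
#'
#' When a simulation is created with `sim$event_log <- list()` before
#' running (the debug flag), every applied kinetic event is recorded.  This
#' writes the log as `time_s, process, element` rows.
#'
#' @param sim a [simulation()] with an event log.
#' @param path output CSV path.
#' @export
write_event_log <- function(sim, path) {
  if (is.null(sim$event_log)) {
    stop("simulation has no event log (set sim$event_log <- list() before running)",
         call. = FALSE)
  }
  log <- do.call(rbind, sim$event_log)
  df <- data.frame(time_s = log[, 1], process = as.integer(log[, 2]),
                   element = as.integer(log[, 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Provenance of a run, sufficient to reproduce it byte-identically: seed,
#' rank count, schedule, content hashes of mesh and model, package version,
#' event/window counters.
#'
#' @param sim a [simulation()] (after running).
#' @param path output JSON path.
#' @param extra named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(sim, path, extra = list()) {
  b <- sim$bound
  manifest <- c(list(
    package = "tetsim",
    version = as.character(utils::packageVersion("tetsim")),
    seed = sim$seed,
    ranks = b$partition$n_ranks,
    operator = sim$operator,
    use_components = isTRUE(sim$use_components),
    schedule = list(t = sim$t, efield_dt = sim$efield_dt, dt_rd = sim$dt_rd,
                    alpha_rd = sim$alpha_rd),
    mesh_hash = content_hash(list(b$mesh$vertices, b$mesh$tets, b$mesh$tris,
                                  b$mesh$tet_tags, b$mesh$tri_tags)),
    model_hash = content_hash(serialize_model(b$model)),
    n_tets = b$n_tet, n_kinetic_processes = b$n_proc,
    event_count = sim$event_count, window_count = sim$window_count
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# Content hash of an R object (stable across sessions for plain data).
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # Fowler-Noll-Vo over the serialized bytes, in double arithmetic
  h <- 2166136261
  for (chunk in split(as.integer(raw),
                      ceiling(seq_along(raw) / 8192))) {
    for (b in chunk) h <- ((h * 16777619) %% 2^32 + b) %% 2^32
  }
  sprintf("fnv1-%08x", as.integer(h %% 2^31))
}

#' Compare two simulation run ensembles
#'
#' The validation pipeline: extract a scalar feature per run from each trace
#' set, compare feature distributions with the batched all-pairs
#' Cramér-von Mises procedure, and (optionally) compare the trace means via
#' mutual confidence bands.  The verdict rejects only when significantly
#' more than `alpha` of the p-values fall below `alpha`.
#'
#' @param a,b [trace_set()]s, or paths to trace CSV files.
#' @param feature `"endpoint"` (last sample of each run), `"peak_heights"`
#'   or `"peak_times"` (k-th peak per run, per [detect_peaks()]).
#' @param peak_number which peak to use for peak features.
#' @param batch_size batch size for [cvm_batch_compare()].
#' @param min_prominence,min_separation peak-detection parameters.
#' @param ci also run the confidence-band comparison.
#' @return A list of class `run_comparison`: per-feature [cvm_batch_compare()]
#'   summaries, optional CI verdict, and the overall `reject`.
#' @export
compare_runs <- function(a, b, feature = "endpoint", peak_number = 1L,
                         batch_size = 10, min_prominence = 0.010,
                         min_separation = 0.002, ci = FALSE) {
  if (is.character(a)) a <- read_traces(a)
  if (is.character(b)) b <- read_traces(b)
  if (!identical(a$probe, b$probe)) {
    stop(sprintf("probe mismatch: '%s' vs '%s'", a$probe, b$probe),
         call. = FALSE)
  }
  extract <- function(ts) {
    switch(feature,
      endpoint = ts$traces[, ncol(ts$traces)],
      peak_heights = apply(ts$traces, 1, function(v) {
        p <- detect_peaks(v, ts$dt, min_prominence, min_separation, ts$t0)
        if (nrow(p) >= peak_number) p$height[peak_number] else NA_real_
      }),
      peak_times = apply(ts$traces, 1, function(v) {
        p <- detect_peaks(v, ts$dt, min_prominence, min_separation, ts$t0)
        if (nrow(p) >= peak_number) p$time_s[peak_number] else NA_real_
      }),
      stop("unknown feature: ", feature, call. = FALSE))
  }
  fa <- extract(a); fb <- extract(b)
  if (anyNA(fa) || anyNA(fb)) {
    stop("feature undefined for some runs (missing peak); reduce peak_number",
         call. = FALSE)
  }
  cvm <- cvm_batch_compare(fa, fb, batch_size = batch_size)
  out <- list(feature = feature, n_a = length(fa), n_b = length(fb),
              cvm = list(median_p = cvm$median,
                         fraction_below = cvm$fraction_below,
                         threshold = cvm$threshold,
                         reject = cvm$reject),
              p_values = cvm$p_values)
  if (ci) {
    out$ci <- ci_band_compare(a, b)
    out$reject <- cvm$reject || out$ci$reject
  } else {
    out$reject <- cvm$reject
  }
  class(out) <- "run_comparison"
  out
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("<run_comparison> feature '%s' (%d vs %d runs): median p %.3f, %.2f%% below 1%%: %s\n",
              x$feature, x$n_a, x$n_b, x$cvm$median_p,
              100 * x$cvm$fraction_below,
              if (x$reject) "REJECT" else "not rejected"))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param comparison a [compare_runs()] result.
#' @param path output path.
#' @export
write_comparison_report <- function(comparison, path) {
  rep <- unclass(comparison)
  rep$p_values <- NULL
  rep$p_value_quartiles <- as.list(stats::quantile(comparison$p_values,
                                                   c(0.25, 0.5, 0.75)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
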