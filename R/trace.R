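#' Construct a recording trace
#'
#' A `trace` is a uniformly sampled voltage or current series together with
#' its sampling interval, recording mode and free-form metadata.  Voltage
#' traces are in mV, current traces in pA (outward positive).
#'
#' @param samples Numeric vector of samples (mV for voltage, pA for current).
#' @param dt Sampling interval in seconds (e.g. `5e-5` for 20 kHz).
#' @param signal `"voltage"` or `"current"`.
#' @param mode Recording configuration: `"cell_attached"`, `"whole_cell"` or
#'   `"perforated"`.
#' @param meta Named list of free-form metadata (cell id, genotype, region,
#'   `ljp_corrected` flag, ...).
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 2000)) * 20 - 50,
#'             dt = 5e-5, signal = "voltage", mode = "whole_cell")
#' tr
#' @export
trace <- function(samples, dt,
                  signal = c("voltage", "current"),
                  mode = c("whole_cell", "cell_attached", "perforated"),
                  meta = list()) {
  signal <- match.arg(signal)
  mode <- match.arg(mode)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace: 'samples' must be non-empty")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("trace: 'dt' must be a single positive number (seconds)")
  if (!is.list(meta)) stop("trace: 'meta' must be a list")
  structure(
    list(samples = samples, dt = dt, signal = signal, mode = mode,
         units = if (signal == "voltage") "mV" else "pA", meta = meta),
    class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %s (%s), mode=%s, n=%d, dt=%g s (%.6g s span)\n",
              x$signal, x$units, x$mode, length(x$samples), x$dt,
              trace_span(x)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Trace time axis and span
#'
#' `trace_times()` returns the sample times in seconds (first sample at 0);
#' `trace_span()` the total duration in seconds.
#'
#' @param x A [trace()].
#' @return Numeric vector of times, or a single duration.
#' @export
trace_times <- function(x) (seq_along(x$samples) - 1L) * x$dt

#' @rdname trace_times
#' @export
trace_span <- function(x) (length(x$samples) - 1L) * x$dt

#' Read a trace from a columnar text file
#'
#' The on-disk format is CSV or TSV with a metadata header of `#key=value`
#' lines followed by `time_s,value` rows.  Mandatory header keys are
#' `signal` and `units`; `mode` defaults to `whole_cell`.  The time column
#' must be strictly increasing and uniform to within `1e-6` relative
#' tolerance; `dt` is inferred from it.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return A [trace()].
#' @export
read_trace <- function(path, format = NULL) {
  format <- infer_format(path, format)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_header(hdr)
  if (is.null(meta$units)) stop("read_trace: header is missing 'units' (", path, ")")
  if (is.null(meta$signal))
    meta$signal <- if (identical(meta$units, "mV")) "voltage" else "current"
  sep <- if (format == "csv") "," else "\t"
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  dat <- utils::read.table(text = body, sep = sep, header = TRUE)
  if (ncol(dat) < 2L) stop("read_trace: expected time and value columns")
  tt <- dat[[1]]; vv <- dat[[2]]
  if (length(tt) > 1L) {
    dts <- diff(tt)
    if (any(dts <= 0))
      stop("read_trace: time not strictly increasing at row ",
           which(dts <= 0)[1] + 1L)
    rel <- abs(dts - dts[1]) / dts[1]
    if (any(rel > 1e-6))
      stop("read_trace: non-uniform sampling at row ",
           which(rel > 1e-6)[1] + 1L,
           " (dt = ", format(dts[which(rel > 1e-6)[1]]), ", expected ",
           format(dts[1]), ")")
    dt <- mean(dts)
  } else {
    if (is.null(meta$dt)) stop("read_trace: single-row file needs a '#dt=' header")
    dt <- as.numeric(meta$dt)
  }
  expected_units <- if (meta$signal == "voltage") "mV" else "pA"
  if (!identical(meta$units, expected_units))
    stop("read_trace: units '", meta$units, "' inconsistent with signal '",
         meta$signal, "' (expected ", expected_units, ")")
  mode <- if (is.null(meta$mode)) "whole_cell" else meta$mode
  extra <- meta[setdiff(names(meta), c("units", "signal", "mode", "dt"))]
  trace(vv, dt = dt, signal = meta$signal, mode = mode, meta = extra)
}

#' Write a trace to a columnar text file
#'
#' Inverse of [read_trace()]: `#key=value` metadata header followed by
#' `time_s,value` rows.  Round-trips samples to better than 1e-9 and all
#' metadata keys.
#'
#' @param x A [trace()].
#' @param path Output file path.
#' @param format `"csv"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "trace"))
  format <- infer_format(path, format)
  sep <- if (format == "csv") "," else "\t"
  hdr <- c(sprintf("#signal=%s", x$signal),
           sprintf("#units=%s", x$units),
           sprintf("#mode=%s", x$mode),
           sprintf("#dt=%.12g", x$dt),
           vapply(names(x$meta),
                  function(k) sprintf("#%s=%s", k, format(x$meta[[k]])),
                  character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste("time_s", "value", sep = sep), con)
  writeLines(paste(sprintf("%.12g", trace_times(x)),
                   sprintf("%.12g", x$samples), sep = sep), con)
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "tsv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) ext else "csv"
}

parse_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2L) next
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

#' Construct a protocol sweep set
#'
#' A `sweep_set` bundles repeated protocol sweeps (all sharing `dt` and
#' length) with the command-step descriptor: holding level, step level,
#' step onset and duration.  Step levels are mV in voltage clamp and pA in
#' current clamp.
#'
#' @param sweeps List of [trace()] objects (all same `dt` and length).
#' @param holding Holding level (mV or pA).
#' @param step Step level, scalar or one value per sweep (mV or pA).
#' @param onset_s Step onset in seconds from sweep start.
#' @param duration_s Step duration in seconds.
#' @param step_units `"mV"` or `"pA"`.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, holding, step, onset_s, duration_s,
                      step_units = c("mV", "pA")) {
  step_units <- match.arg(step_units)
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "trace")))
    stop("sweep_set: 'sweeps' must be a non-empty list of trace objects")
  dts <- vapply(sweeps, `[[`, 0, "dt")
  ns <- vapply(sweeps, function(s) length(s$samples), 0L)
  if (diff(range(dts)) > 1e-12 || length(unique(ns)) != 1L)
    stop("sweep_set: all sweeps must share dt and length")
  if (!(length(step) %in% c(1L, length(sweeps))))
    stop("sweep_set: 'step' must be scalar or one value per sweep")
  span <- (ns[1] - 1L) * dts[1]
  if (onset_s + duration_s > span + 1e-12)
    stop("sweep_set: step onset + duration exceeds the sweep span")
  structure(
    list(sweeps = sweeps,
         command = list(holding = holding, step = rep(step, length.out = length(sweeps)),
                        onset_s = onset_s, duration_s = duration_s,
                        step_units = step_units)),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cmd <- x$command
  cat(sprintf(
    "<sweep_set> %d sweeps, hold %g %s, step %s %s, onset %g s, dur %g s\n",
    length(x$sweeps), cmd$holding, cmd$step_units,
    paste(format(unique(cmd$step)), collapse = "/"), cmd$step_units,
    cmd$onset_s, cmd$duration_s))
  invisible(x)
}

#' Read or write a sweep set as a directory of trace files
#'
#' Sweeps are stored as `sweep_001.csv`, ... plus a `protocol.yaml`
#' describing the command step.
#'
#' @param path Directory path.
#' @param x A [sweep_set()] (for writing).
#' @return A [sweep_set()], or `path` invisibly for the writer.
#' @export
read_sweep_set <- function(path) {
  proto <- yaml::read_yaml(file.path(path, "protocol.yaml"))
  files <- sort(list.files(path, pattern = "^sweep_\\d+\\.(csv|tsv)$",
                           full.names = TRUE))
  if (!length(files)) stop("read_sweep_set: no sweep files under ", path)
  sweep_set(lapply(files, read_trace),
            holding = proto$holding, step = unlist(proto$step),
            onset_s = proto$onset_s, duration_s = proto$duration_s,
            step_units = proto$step_units)
}

#' @rdname read_sweep_set
#' @export
write_sweep_set <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(x$command, file.path(path, "protocol.yaml"))
  for (i in seq_along(x$sweeps))
    write_trace(x$sweeps[[i]], file.path(path, sprintf("sweep_%03d.csv", i)))
  invisible(path)
}
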