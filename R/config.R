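#' Pipeline configuration
#'
#' `default_config()` returns the full set of tunable parameters with their
#' documented defaults; `read_config()`/`write_config()` serialize it as a
#' YAML document.  Values supplied in `...` (or in the file) override the
#' defaults by name, nested lists merging recursively.
#'
#' Defaults that restate a published analysis convention:
#' `spikes$threshold_mV = -10` (upward crossing detection),
#' `spikes$dvdt_criterion = 10` mV/ms (apparent threshold),
#' `spikes$rate_bin_ms = 10` (rate from mean count per 10 ms bin),
#' `isi$n_points = 1000` (per-ISI resampling), `isi$mahp_window_ms =
#' c(10, 100)` after the trajectory minimum, `patchseq$fdr_cutoff = 0.1`
#' and `patchseq$fc_cutoff = 1.25`, `behavior$acquisition_criterion = 70`
#' (percent) by `behavior$max_day = 14`, and `ljp$vj_whole_cell = -17.1`
#' mV as the published offline correction.  The remainder are repository
#' conventions (windows, filter orders, integration bounds) documented in
#' the methods vignette.
#'
#' @param ... Name-value overrides, e.g. `spikes = list(threshold_mV = -15)`.
#' @param path File path for the YAML reader/writer.
#' @param config A configuration list (for the writer).
#' @return A nested named list of class `skpatch_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    spikes = list(
      threshold_mV = -10,        # upward-crossing detection level
      dvdt_criterion = 10,       # mV/ms, apparent threshold criterion
      rate_bin_ms = 10,          # rate = mean count per bin / bin length
      cv_segment_s = 10,         # CV_ISI averaged over segments this long
      refractory_ms = 2,         # event-detection lockout
      sg_window_ms = 1,          # Savitzky-Golay smoothing window
      sg_order = 3),
    isi = list(
      n_points = 1000,
      mahp_window_ms = c(10, 100)),
    protocol = list(
      baseline_ms = 50,          # pre-step baseline window
      tail_window_ms = 1000,     # max AUC integration window after offset
      recross_ms = 50,           # early stop: baseline re-crossed this long
      fi_fit_range_pA = c(0, 60),
      rebound_window_s = 2),
    ljp = list(
      temperature_K = 298.15,
      vj_whole_cell = -17.1),    # published offline correction, mV
    patchseq = list(
      fdr_cutoff = 0.1,
      fc_cutoff = 1.25,
      pseudo_count = 0.5,
      min_count = 1,
      min_fraction = 0.8,
      positive_markers = c("Th", "Slc6a3", "Slc18a2"),
      negative_markers = c("Pvalb", "Tmem119", "P2ry12", "Aldh1l1")),
    behavior = list(
      acquisition_criterion = 70,
      max_day = 14,
      attention_bin = 3,
      count_timeout_pokes = TRUE))
  out <- merge_config(cfg, list(...))
  class(out) <- c("skpatch_config", "list")
  out
}

merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], over[[k]])
    else base[[k]] <- over[[k]]
  }
  base
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
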