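#' Construct a spike train
#'
#' Ordered event times (seconds) detected from a trace, together with the
#' span of the source recording.
#'
#' @param times_s Strictly increasing event times (s).
#' @param span_s Duration of the source recording (s).
#' @param method Detection method label.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times_s, span_s, method = "manual") {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s, strictly = TRUE))
    stop("spike_train: times must be strictly increasing")
  if (length(times_s) && (min(times_s) < 0 || max(times_s) > span_s + 1e-12))
    stop("spike_train: times must lie within [0, span_s]")
  structure(list(times_s = times_s, span_s = span_s, method = method),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events over %.3f s (%s)\n",
              length(x$times_s), x$span_s, x$method))
  invisible(x)
}

#' Detect action currents in a cell-attached recording
#'
#' Smooths the current trace with a Savitzky-Golay filter and detects
#' action currents as negative-going peaks (events in the positive
#' direction are never counted).  The detection threshold is either a
#' fixed amplitude in pA or, by default, adaptive at `k_mad` robust
#' standard deviations of the smoothed trace.  A refractory lockout
#' suppresses secondary minima.
#'
#' @param x A current [trace()] in cell-attached mode.
#' @param threshold_pA Positive detection amplitude (pA); events are
#'   minima below `-threshold_pA`.  `NULL` for adaptive.
#' @param k_mad Adaptive threshold multiplier (default 5 robust SDs).
#' @param sg_window_ms,sg_order Savitzky-Golay window (ms) and polynomial
#'   order.
#' @param refractory_ms Lockout after each detected event (ms).
#' @return A [spike_train()] with times at the peak minima.
#' @export
detect_action_currents <- function(x, threshold_pA = NULL, k_mad = 5,
                                   sg_window_ms = 1, sg_order = 3,
                                   refractory_ms = 2) {
  stopifnot(inherits(x, "trace"))
  if (x$signal != "current" || x$mode != "cell_attached")
    stop("detect_action_currents: needs a cell-attached current trace")
  if (trace_span(x) < 1)
    stop("detect_action_currents: trace shorter than 1 s")
  v <- x$samples
  rng <- range(v)
  if (diff(rng) > 0) {
    clipped <- mean(v == rng[1] | v == rng[2])
    if (clipped > 0.01)
      warning(sprintf("detect_action_currents: %.1f%% of samples at range limits (saturation?)",
                      100 * clipped))
  }
  n_win <- max(sg_order + 2, round(sg_window_ms / 1000 / x$dt))
  if (n_win %% 2 == 0) n_win <- n_win + 1
  sm <- signal::sgolayfilt(v, p = sg_order, n = n_win)
  if (is.null(threshold_pA)) {
    s <- stats::mad(sm)
    if (s == 0) return(spike_train(numeric(0), trace_span(x), "action_current"))
    threshold_pA <- k_mad * s
  }
  thr <- -abs(threshold_pA)
  below <- which(sm < thr)
  if (!length(below))
    return(spike_train(numeric(0), trace_span(x), "action_current"))
  # local minima among sub-threshold samples, then refractory lockout
  n <- length(sm)
  is_min <- below[below > 1 & below < n]
  is_min <- is_min[sm[is_min] <= sm[is_min - 1] & sm[is_min] < sm[is_min + 1]]
  if (!length(is_min))
    return(spike_train(numeric(0), trace_span(x), "action_current"))
  lock <- max(1L, round(refractory_ms / 1000 / x$dt))
  keep <- integer(0)
  last <- -Inf
  for (i in is_min) {
    if (i - last >= lock) {
      keep <- c(keep, i)
      last <- i
    } else if (sm[i] < sm[keep[length(keep)]]) {
      keep[length(keep)] <- i   # deeper minimum within the lockout wins
      last <- i
    }
  }
  spike_train((keep - 1L) * x$dt, trace_span(x), "action_current")
}

#' Detect spikes by upward threshold crossing
#'
#' One event per upward crossing of the voltage threshold (default -10
#' mV); no further event is registered until the trace has re-crossed
#' below the threshold.  Event times are at the crossing sample.
#'
#' @param x A voltage [trace()].
#' @param threshold_mV Crossing level (mV).
#' @return A [spike_train()].
#' @export
detect_spikes <- function(x, threshold_mV = -10) {
  stopifnot(inherits(x, "trace"))
  if (x$signal != "voltage")
    stop("detect_spikes: needs a voltage trace")
  v <- x$samples
  if (threshold_mV < min(v) || threshold_mV > max(v)) {
    if (max(v) < threshold_mV)
      warning("detect_spikes: threshold above the observed voltage range")
    return(spike_train(numeric(0), trace_span(x), "voltage_crossing"))
  }
  above <- v >= threshold_mV
  idx <- which(above[-1] & !above[-length(v)]) + 1L
  spike_train((idx - 1L) * x$dt, trace_span(x), "voltage_crossing")
}

#' Firing rate and ISI regularity
#'
#' The rate estimator is the mean spike count per bin (default 10 ms)
#' divided by the bin length, over bins tiling the recording.  The
#' coefficient of variation of the interspike interval is computed from
#' the ISIs whose onset falls in each analysis segment (default 10 s) and
#' averaged across segments with at least three ISIs, which keeps the
#' estimate robust to slow rate drift.  With fewer than three spikes the
#' CV is flagged undefined.
#'
#' @param spikes A [spike_train()].
#' @param rate_bin_ms Rate bin length (ms).
#' @param cv_segment_s CV analysis segment length (s).
#' @return A list of class `firing_stats`: `rate_hz`, `cv_isi`,
#'   `cv_defined`, `n_spikes`, `window_s`.
#' @export
firing_stats <- function(spikes, rate_bin_ms = 10, cv_segment_s = 10) {
  stopifnot(inherits(spikes, "spike_train"))
  span <- spikes$span_s
  bin <- rate_bin_ms / 1000
  n_bins <- max(1L, floor(span / bin))
  counts <- tabulate(pmin(n_bins, floor(spikes$times_s / bin) + 1L), n_bins)
  rate <- mean(counts) / bin
  st <- spikes$times_s
  if (length(st) < 3) {
    return(structure(list(rate_hz = rate, cv_isi = NA_real_,
                          cv_defined = FALSE, n_spikes = length(st),
                          window_s = span), class = "firing_stats"))
  }
  isi <- diff(st)
  onset <- st[-length(st)]
  seg <- floor(onset / cv_segment_s)
  cvs <- vapply(split(isi, seg), function(d)
    if (length(d) >= 3) sd(d) / mean(d) else NA_real_, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  cv <- if (length(cvs)) mean(cvs) else sd(isi) / mean(isi)
  structure(list(rate_hz = rate, cv_isi = cv, cv_defined = TRUE,
                 n_spikes = length(st), window_s = span),
            class = "firing_stats")
}

#' @export
print.firing_stats <- function(x, ...) {
  cat(sprintf("<firing_stats> rate %.3f Hz, CV_ISI %s, n = %d over %.1f s\n",
              x$rate_hz,
              if (x$cv_defined) sprintf("%.3f", x$cv_isi) else "undefined",
              x$n_spikes, x$window_s))
  invisible(x)
}

#' Apparent spike threshold and width from averaged waveforms
#'
#' Spikes are aligned on their voltage peak, averaged per cell, and the
#' apparent threshold is the voltage at which the rising dV/dt first
#' crosses the criterion (default 10 mV/ms) before the peak.  The width
#' is the full width at half maximum, the half level lying midway between
#' threshold and peak, with sub-sample linear interpolation at the two
#' half-level crossings.
#'
#' @param x A voltage [trace()] with `dt <= 1e-4` s.
#' @param spikes A [spike_train()] (crossing or peak times; the peak is
#'   re-located within `peak_search_ms`).
#' @param dvdt_criterion Threshold criterion (mV/ms).
#' @param window_ms Half-width of the alignment window around the peak (ms).
#' @param peak_search_ms Forward search for the peak from each event time (ms).
#' @return A list of class `spike_waveform`: `threshold_mV`, `width_ms`,
#'   `n_spikes_used`, `waveform` (average, mV), `dt_ms`.
#' @export
spike_waveform_features <- function(x, spikes, dvdt_criterion = 10,
                                    window_ms = 10, peak_search_ms = 3) {
  stopifnot(inherits(x, "trace"), inherits(spikes, "spike_train"))
  if (x$dt > 1e-4)
    stop("spike_waveform_features: sampling too coarse (dt > 0.1 ms)")
  if (!length(spikes$times_s))
    stop("spike_waveform_features: no spikes")
  v <- x$samples
  dt_ms <- x$dt * 1000
  hw <- round(window_ms / dt_ms)
  srch <- round(peak_search_ms / dt_ms)
  peaks <- integer(0)
  for (t in spikes$times_s) {
    i <- round(t / x$dt) + 1L
    j <- min(length(v), i + srch)
    p <- i + which.max(v[i:j]) - 1L
    if (p - hw >= 1 && p + hw <= length(v)) peaks <- c(peaks, p)
  }
  if (!length(peaks))
    stop("spike_waveform_features: no complete spike windows")
  wf <- rowMeans(vapply(peaks, function(p) v[(p - hw):(p + hw)],
                        numeric(2 * hw + 1)))
  pk_i <- hw + 1L
  dvdt <- c(NA, diff(wf)) / dt_ms
  cross <- which(dvdt[seq_len(pk_i)] >= dvdt_criterion)
  if (!length(cross)) {
    return(structure(list(threshold_mV = NA_real_, width_ms = NA_real_,
                          n_spikes_used = length(peaks), waveform = wf,
                          dt_ms = dt_ms), class = "spike_waveform"))
  }
  th_i <- cross[1]
  threshold <- wf[th_i]
  half <- (threshold + wf[pk_i]) / 2
  # rising half-crossing (between th_i and peak), falling after the peak
  up <- which(wf[th_i:pk_i] >= half)[1] + th_i - 1L
  t_up <- if (up > 1 && wf[up] > wf[up - 1])
    (up - 1) - (wf[up] - half) / (wf[up] - wf[up - 1]) else up - 1
  after <- wf[pk_i:length(wf)]
  dn <- which(after < half)[1] + pk_i - 1L
  width <- if (is.na(dn)) NA_real_ else {
    t_dn <- (dn - 2) + (wf[dn - 1] - half) / (wf[dn - 1] - wf[dn])
    (t_dn - t_up) * dt_ms
  }
  structure(list(threshold_mV = threshold, width_ms = width,
                 n_spikes_used = length(peaks), waveform = wf,
                 dt_ms = dt_ms), class = "spike_waveform")
}

#' Averaged interspike-interval voltage trajectory
#'
#' Each ISI voltage segment is resampled to exactly `n_points` points by
#' linear interpolation on the half-open interval from one spike to the
#' next, rows are averaged into the per-cell trajectory, and two scalar
#' features are read off the average row: the minimum ISI voltage, and
#' the mAHP voltage defined as the mean of the average row from 10 ms to
#' 100 ms after the minimum (times mapped back through the cell's mean
#' ISI duration).  Grand averages across cells are plain means of per-cell
#' average rows.
#'
#' @param x A voltage [trace()].
#' @param spikes A [spike_train()] with at least 2 events.
#' @param n_points Points per resampled ISI (default 1000).
#' @param mahp_window_ms Window after the trajectory minimum (ms).
#' @return An object of class `isi_trajectory`: `rows` (n_isi x
#'   n_points), `average`, `min_mV`, `min_time_ms`, `mahp_mV`,
#'   `mean_isi_ms`, `mahp_truncated`, `n_isi`.
#' @export
isi_voltage_trajectory <- function(x, spikes, n_points = 1000,
                                   mahp_window_ms = c(10, 100)) {
  stopifnot(inherits(x, "trace"), inherits(spikes, "spike_train"))
  st <- spikes$times_s
  if (length(st) < 2)
    stop("isi_voltage_trajectory: need at least 2 spikes")
  rows <- list()
  for (i in seq_len(length(st) - 1L)) {
    t0 <- st[i]; t1 <- st[i + 1L]
    if ((t1 - t0) < 2 * x$dt) next      # fewer than 2 samples: excluded
    xo <- t0 + (0:(n_points - 1L)) / n_points * (t1 - t0)
    i0 <- max(1L, floor(t0 / x$dt))     # interpolate on the local slice only
    i1 <- min(length(x$samples), ceiling(t1 / x$dt) + 2L)
    rows[[length(rows) + 1L]] <-
      approx((i0:i1 - 1L) * x$dt, x$samples[i0:i1], xout = xo)$y
  }
  if (!length(rows))
    stop("isi_voltage_trajectory: no usable ISI (all shorter than 2 samples)")
  m <- do.call(rbind, rows)
  avg <- colMeans(m)
  mean_isi_ms <- mean(diff(st)[diff(st) >= 2 * x$dt]) * 1000
  tp <- (seq_len(n_points) - 1L) / n_points * mean_isi_ms  # point times, ms
  imin <- which.min(avg)
  min_t <- tp[imin]
  w0 <- min_t + mahp_window_ms[1]
  w1 <- min_t + mahp_window_ms[2]
  truncated <- w1 > mean_isi_ms
  sel <- tp >= w0 & tp <= min(w1, mean_isi_ms)
  mahp <- if (any(sel)) mean(avg[sel]) else NA_real_
  structure(list(rows = m, average = avg, min_mV = avg[imin],
                 min_time_ms = min_t, mahp_mV = mahp,
                 mean_isi_ms = mean_isi_ms, mahp_truncated = truncated,
                 n_isi = nrow(m)),
            class = "isi_trajectory")
}

#' @export
print.isi_trajectory <- function(x, ...) {
  cat(sprintf(
    "<isi_trajectory> %d ISIs, mean %.1f ms; min %.2f mV @ %.1f ms; mAHP %.2f mV%s\n",
    x$n_isi, x$mean_isi_ms, x$min_mV, x$min_time_ms, x$mahp_mV,
    if (x$mahp_truncated) " (window truncated)" else ""))
  invisible(x)
}

#' Per-cell spike feature summary
#'
#' Convenience wrapper running the whole feature chain on one voltage
#' trace: liquid-junction correction if the trace is an uncorrected
#' whole-cell recording (using `config$ljp$vj_whole_cell`), spike
#' detection, firing statistics, waveform features and the ISI
#' trajectory.  Returns a one-row data frame ready for [write_report()].
#'
#' @param x A voltage [trace()].
#' @param config A [default_config()] list.
#' @param cell_id Identifier echoed in the output row.
#' @return A one-row `data.frame` with columns `cell_id`, `rate_hz`,
#'   `cv_isi`, `threshold_mV`, `width_ms`, `min_isi_mV`, `mahp_mV`,
#'   `n_spikes`.
#' @export
cell_features <- function(x, config = default_config(), cell_id = "cell") {
  stopifnot(inherits(x, "trace"))
  if (x$mode == "whole_cell" && !isTRUE(x$meta$ljp_corrected))
    x <- apply_ljp_correction(x, config$ljp$vj_whole_cell)
  sp <- detect_spikes(x, threshold_mV = config$spikes$threshold_mV)
  fs <- firing_stats(sp, rate_bin_ms = config$spikes$rate_bin_ms,
                     cv_segment_s = config$spikes$cv_segment_s)
  wf <- if (length(sp$times_s))
    spike_waveform_features(x, sp, dvdt_criterion = config$spikes$dvdt_criterion)
  else list(threshold_mV = NA_real_, width_ms = NA_real_)
  tj <- if (length(sp$times_s) >= 2)
    isi_voltage_trajectory(x, sp, n_points = config$isi$n_points,
                           mahp_window_ms = config$isi$mahp_window_ms)
  else list(min_mV = NA_real_, mahp_mV = NA_real_)
  data.frame(cell_id = cell_id, rate_hz = fs$rate_hz, cv_isi = fs$cv_isi,
             threshold_mV = wf$threshold_mV, width_ms = wf$width_ms,
             min_isi_mV = tj$min_mV, mahp_mV = tj$mahp_mV,
             n_spikes = fs$n_spikes, stringsAsFactors = FALSE)
}
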