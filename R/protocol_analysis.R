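#' SK tail-current metrics
#'
#' Averages the sweeps of a voltage-clamp tail protocol and measures the
#' deactivation tail after step offset: baseline current (mean over the
#' pre-step window), maximal baseline-subtracted amplitude, and the
#' trapezoidal area under the baseline-subtracted curve, reported as
#' charge in pC.  The integration window runs from step offset to
#' `window_ms`, or until the baseline has been re-crossed for
#' `recross_ms` consecutive milliseconds, whichever is earlier.
#'
#' @param sweeps A [sweep_set()] of current sweeps with step metadata.
#' @param baseline_ms Pre-step baseline window (ms).
#' @param window_ms Maximal integration window after step offset (ms).
#' @param recross_ms Early-stop criterion (ms at or below baseline).
#' @return A list of class `tail_metrics`: `baseline_pA`, `amplitude_pA`,
#'   `auc_pC`, `window_ms` (actually integrated), `n_sweeps`.
#' @export
tail_current_metrics <- function(sweeps, baseline_ms = 50,
                                 window_ms = 1000, recross_ms = 50) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (sweeps$sweeps[[1]]$signal != "current")
    stop("tail_current_metrics: current sweeps required")
  cmd <- sweeps$command
  dt <- sweeps$sweeps[[1]]$dt
  avg <- rowMeans(vapply(sweeps$sweeps, `[[`, numeric(length(sweeps$sweeps[[1]]$samples)),
                         "samples"))
  tt <- (seq_along(avg) - 1L) * dt
  offset <- cmd$onset_s + cmd$duration_s
  if (offset >= max(tt))
    stop("tail_current_metrics: step offset beyond the trace span")
  base_sel <- tt >= (cmd$onset_s - baseline_ms / 1000) & tt < cmd$onset_s
  if (!any(base_sel)) stop("tail_current_metrics: empty baseline window")
  baseline <- mean(avg[base_sel])
  post <- which(tt >= offset & tt <= offset + window_ms / 1000)
  y <- avg[post] - baseline
  amp <- max(y)
  # early stop once the baseline is re-crossed for recross_ms
  n_rec <- max(1L, round(recross_ms / 1000 / dt))
  below <- y <= 0
  run <- 0L
  stop_i <- length(y)
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= n_rec) { stop_i <- i; break }
  }
  sel <- seq_len(stop_i)
  auc <- pracma::trapz(tt[post[sel]], y[sel])   # pA * s = pC
  structure(list(baseline_pA = baseline, amplitude_pA = amp, auc_pC = auc,
                 window_ms = (stop_i - 1L) * dt * 1000,
                 n_sweeps = length(sweeps$sweeps)),
            class = "tail_metrics")
}

#' @export
print.tail_metrics <- function(x, ...) {
  cat(sprintf("<tail_metrics> baseline %.1f pA, amplitude %.1f pA, AUC %.3f pC (%.0f ms)\n",
              x$baseline_pA, x$amplitude_pA, x$auc_pC, x$window_ms))
  invisible(x)
}

#' Frequency-current curve and gain
#'
#' Counts spikes during the current step of each sweep (via
#' [detect_spikes()]), converts to frequency, and fits the gain as the
#' ordinary least-squares slope of frequency against injected current
#' using only steps inside `fit_range_pA` (default 0-60 pA).  The gain is
#' flagged undefined with fewer than three usable steps in range.
#'
#' @param sweeps A [sweep_set()] of voltage sweeps, `step` in pA.
#' @param fit_range_pA Range of steps entering the slope fit.
#' @param threshold_mV Spike detection threshold.
#' @return A list of class `fi_curve`: `step_pA`, `freq_hz`,
#'   `gain_hz_per_pA`, `gain_defined`.
#' @export
fi_gain <- function(sweeps, fit_range_pA = c(0, 60), threshold_mV = -10) {
  stopifnot(inherits(sweeps, "sweep_set"))
  cmd <- sweeps$command
  if (cmd$step_units != "pA")
    stop("fi_gain: sweeps must carry current steps (pA)")
  t0 <- cmd$onset_s
  t1 <- cmd$onset_s + cmd$duration_s
  freq <- vapply(sweeps$sweeps, function(s) {
    # a subthreshold step legitimately has no crossings: no warning wanted
    st <- suppressWarnings(detect_spikes(s, threshold_mV))$times_s
    sum(st >= t0 & st < t1) / cmd$duration_s
  }, numeric(1))
  steps <- cmd$step
  # aggregate repeated steps before fitting so replicates average out
  agg <- tapply(freq, steps, mean)
  s_u <- as.numeric(names(agg))
  in_rng <- s_u >= fit_range_pA[1] & s_u <= fit_range_pA[2]
  if (sum(in_rng) < 3) {
    gain <- NA_real_; defined <- FALSE
  } else {
    gain <- unname(coef(lm(agg[in_rng] ~ s_u[in_rng]))[2])
    if (is.na(gain)) gain <- 0       # degenerate: single step level
    defined <- TRUE
  }
  structure(list(step_pA = s_u, freq_hz = as.numeric(agg),
                 gain_hz_per_pA = gain, gain_defined = defined),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("<fi_curve> %d steps; gain %s Hz/pA\n", length(x$step_pA),
              if (x$gain_defined) sprintf("%.4f", x$gain_hz_per_pA) else "undefined"))
  invisible(x)
}

#' Bi-exponential A-current inactivation fit
#'
#' Fits `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` to the decaying outward
#' transient by Levenberg-Marquardt nonlinear least squares.  Starting
#' values come from a two-segment log-linear seed (early/late halves of
#' the log-transformed, offset-subtracted decay) plus a deterministic
#' grid of multiplicative jitters in [0.3, 3]; the best converged start
#' wins.  Time constants are returned ordered `tau1 <= tau2`.  A fit is
#' flagged degenerate when one amplitude falls below 1% of the other or
#' the time constants are within 20% of each other (the mono-exponential
#' limit).
#'
#' @param x A current [trace()] containing the transient.
#' @param fit_start_s Fit window start (s); default at the current maximum.
#' @param fit_window_ms Fit window length (ms).
#' @return A list of class `a_current_fit`: `a1_pA`, `tau1_ms`, `a2_pA`,
#'   `tau2_ms`, `offset_pA`, `r_squared`, `degenerate`.
#' @export
a_current_inactivation <- function(x, fit_start_s = NULL, fit_window_ms = 1000) {
  stopifnot(inherits(x, "trace"))
  if (x$signal != "current") stop("a_current_inactivation: current trace required")
  tt <- trace_times(x)
  if (is.null(fit_start_s)) fit_start_s <- tt[which.max(x$samples)]
  sel <- tt >= fit_start_s & tt <= fit_start_s + fit_window_ms / 1000
  if (sum(sel) < 10) stop("a_current_inactivation: fit window too short")
  t_ms <- (tt[sel] - fit_start_s) * 1000
  y <- x$samples[sel]
  if (y[1] <= mean(tail(y, max(3, length(y) %/% 10))))
    stop("a_current_inactivation: no decaying transient in the fit window")
  c0 <- mean(tail(y, max(3, length(y) %/% 10)))
  pos <- pmax(y - c0, 1e-9)
  ly <- log(pos)
  n <- length(t_ms)
  early <- seq_len(max(5, n %/% 4))
  late <- seq(max(5, n %/% 2), n)
  fit_seg <- function(i) {
    cf <- coef(lm(ly[i] ~ t_ms[i]))
    tau <- -1 / cf[2]
    list(A = exp(cf[1]), tau = if (is.finite(tau) && tau > 0) tau else max(t_ms) / 3)
  }
  s1 <- fit_seg(early); s2 <- fit_seg(late)
  start0 <- c(a1 = max(s1$A - s2$A, 0.3 * s1$A), tau1 = min(s1$tau, s2$tau),
              a2 = s2$A, tau2 = max(s2$tau, 1.5 * min(s1$tau, s2$tau)))
  jitters <- list(c(1, 1, 1, 1), c(0.3, 0.3, 3, 3), c(3, 3, 0.3, 0.3),
                  c(1, 0.3, 1, 3), c(0.55, 1.8, 1.8, 0.55), c(1.8, 0.55, 0.55, 1.8))
  model <- function(p, t) p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4]) + p[5]
  best <- NULL
  resids <- numeric(0)
  for (j in jitters) {
    st <- c(start0 * j, C = c0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 * exp(-t_ms / tau1) + a2 * exp(-t_ms / tau2) + C,
                        start = as.list(setNames(st, c("a1", "tau1", "a2", "tau2", "C"))),
                        lower = c(0, 1e-3, 0, 1e-3, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    resids <- c(resids, rss)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("a_current_inactivation: no start converged; residuals: ",
         paste(format(resids), collapse = ", "))
  p <- coef(best$fit)
  if (p[["tau1"]] > p[["tau2"]])
    p <- p[c("a2", "tau2", "a1", "tau1", "C")]
  a1 <- unname(p[1]); tau1 <- unname(p[2])
  a2 <- unname(p[3]); tau2 <- unname(p[4])
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  degen <- min(a1, a2) < 0.01 * max(a1, a2) || tau2 / tau1 < 1.2
  structure(list(a1_pA = a1, tau1_ms = tau1, a2_pA = a2, tau2_ms = tau2,
                 offset_pA = unname(p[5]), r_squared = r2,
                 degenerate = degen),
            class = "a_current_fit")
}

#' @export
print.a_current_fit <- function(x, ...) {
  cat(sprintf(
    "<a_current_fit> A1 %.1f pA tau1 %.1f ms | A2 %.1f pA tau2 %.1f ms | C %.1f pA, R2 %.4f%s\n",
    x$a1_pA, x$tau1_ms, x$a2_pA, x$tau2_ms, x$offset_pA, x$r_squared,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Rebound delay after a hyperpolarizing step
#'
#' Time from the offset of a hyperpolarizing current step to the first
#' detected spike, in ms.  Returns `NA` (the "none" sentinel) when no
#' spike occurs within the post-step window.
#'
#' @param x A voltage [trace()].
#' @param step_offset_s Step offset time (s).
#' @param window_s Post-step search window (s, default 2).
#' @param threshold_mV Spike detection threshold.
#' @return Delay in ms, or `NA` if no spike occurred in the window.
#' @export
rebound_delay <- function(x, step_offset_s, window_s = 2, threshold_mV = -10) {
  st <- suppressWarnings(detect_spikes(x, threshold_mV))$times_s
  st <- st[st >= step_offset_s & st <= step_offset_s + window_s]
  if (!length(st)) return(NA_real_)
  (st[1] - step_offset_s) * 1000
}

#' EPSC charge by trapezoidal integration
#'
#' Baseline-subtracted trapezoidal integral of a stimulus-aligned current
#' sweep over the integration window, in pC.  Inward (negative) currents
#' yield negative charge.
#'
#' @param x A current [trace()].
#' @param baseline_window_s Length-2 vector, baseline window (s).
#' @param integration_window_s Length-2 vector, integration window (s).
#' @return Charge in pC.
#' @export
epsc_charge <- function(x, baseline_window_s, integration_window_s) {
  stopifnot(inherits(x, "trace"))
  if (x$signal != "current") stop("epsc_charge: current trace required")
  tt <- trace_times(x)
  bsel <- tt >= baseline_window_s[1] & tt <= baseline_window_s[2]
  isel <- tt >= integration_window_s[1] & tt <= integration_window_s[2]
  if (!any(bsel) || sum(isel) < 2) stop("epsc_charge: empty window")
  baseline <- mean(x$samples[bsel])
  pracma::trapz(tt[isel], x$samples[isel] - baseline)  # pA * s = pC
}

#' Rule-based catecholaminergic cell classification
#'
#' Applies the electrophysiological identification rules for ventral
#' tegmental area dopamine neurons (firing 0.5-8 Hz, spike width > 1.1
#' ms, A-current inactivation time constant 30-300 ms, rebound delay >
#' 250 ms), substantia nigra pars compacta dopamine neurons (1-5 Hz,
#' width > 1.1 ms, fast-inactivating A-current, hyperpolarization-
#' activated current > 100 pA) and locus coeruleus noradrenergic neurons
#' (0.25-6 Hz, slow-inactivating A-current, membrane resistance < 100
#' MOhm).  "Fast" vs "slow" A-current inactivation is mapped to `tau_a`
#' below/above 100 ms.  A missing feature fails its comparisons closed
#' unless the `region` hint names the rule's region, in which case
#' comparisons on missing features are skipped (the anatomical location
#' stands in for the unmeasured fingerprint).  The label is assigned only
#' when exactly one rule set passes; a multi-rule pass returns
#' `unclassified` with a conflict flag.  Every comparison is returned in
#' the rule trace.
#'
#' @param rate_hz Spontaneous firing rate (Hz).
#' @param width_ms Spike width (ms).
#' @param tau_a_ms A-current inactivation time constant (ms), or `NA`.
#' @param rebound_ms Rebound delay (ms), or `NA`.
#' @param ih_pA Hyperpolarization-activated current amplitude (pA), or `NA`.
#' @param rm_mohm Membrane resistance (MOhm), or `NA`.
#' @param region Optional region hint: `"VTA"`, `"SNc"` or `"LC"`.
#' @return A list of class `cell_classification`: `label`, `conflict`,
#'   `rule_trace` (data frame of every comparison).
#' @export
classify_cell <- function(rate_hz, width_ms, tau_a_ms = NA, rebound_ms = NA,
                          ih_pA = NA, rm_mohm = NA, region = NA) {
  if (missing(rate_hz) || missing(width_ms))
    stop("classify_cell: rate_hz and width_ms are required")
  rules <- list(
    VTA_DA = list(region = "VTA", checks = list(
      rate_in_band = list(rate_hz, function(v) v >= 0.5 & v <= 8),
      wide_spike = list(width_ms, function(v) v > 1.1),
      tau_a_band = list(tau_a_ms, function(v) v >= 30 & v <= 300),
      long_rebound = list(rebound_ms, function(v) v > 250))),
    SNc_DA = list(region = "SNc", checks = list(
      rate_in_band = list(rate_hz, function(v) v >= 1 & v <= 5),
      wide_spike = list(width_ms, function(v) v > 1.1),
      fast_ia = list(tau_a_ms, function(v) v < 100),
      ih_large = list(ih_pA, function(v) v > 100))),
    LC_NE = list(region = "LC", checks = list(
      rate_in_band = list(rate_hz, function(v) v >= 0.25 & v <= 6),
      slow_ia = list(tau_a_ms, function(v) v >= 100),
      low_rm = list(rm_mohm, function(v) v < 100))))
  trace_rows <- list()
  passed <- character(0)
  for (lab in names(rules)) {
    rule <- rules[[lab]]
    hinted <- !is.na(region) && identical(region, rule$region)
    ok_all <- TRUE
    for (cn in names(rule$checks)) {
      val <- rule$checks[[cn]][[1]]
      fn <- rule$checks[[cn]][[2]]
      if (is.na(val)) {
        res <- if (hinted) NA else FALSE     # skipped vs fail-closed
        if (!hinted) ok_all <- FALSE
      } else {
        res <- isTRUE(fn(val))
        if (!res) ok_all <- FALSE
      }
      trace_rows[[length(trace_rows) + 1L]] <-
        data.frame(rule = lab, check = cn, value = as.numeric(val),
                   result = if (is.na(res)) "skipped (region hint)"
                            else if (res) "pass" else "fail",
                   stringsAsFactors = FALSE)
    }
    if (ok_all) passed <- c(passed, lab)
  }
  conflict <- length(passed) > 1
  label <- if (length(passed) == 1) passed else "unclassified"
  structure(list(label = label, conflict = conflict,
                 rule_trace = do.call(rbind, trace_rows)),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("<cell_classification> %s%s\n", x$label,
              if (x$conflict) " (conflicting rules)" else ""))
  invisible(x)
}
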