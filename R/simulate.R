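#' Parameters for the conductance-based pacemaker simulator
#'
#' The simulator is a minimal single-compartment membrane model built to
#' reproduce the slow (0.5-4 Hz) pacemaker firing of midbrain dopamine
#' neurons and its dependence on the SK conductance: spike currents (fast
#' Na+, delayed-rectifier K+), a subthreshold Ca2+ current feeding a single
#' calcium pool, a calcium-gated SK K+ current with Hill activation, an
#' A-type K+ current, an ohmic leak, and additive Ornstein-Uhlenbeck
#' current noise.  The calmodulin-phosphorylation factor `phi` right-shifts
#' the SK calcium half-activation (`k_eff = sk_k_half * (1 + 2*phi)`),
#' emulating reduced calcium sensitivity of phosphorylated SK-bound
#' calmodulin; `g_sk` itself is the conductance an SK blocker removes.
#'
#' @param g_na,g_k,g_ca,g_sk,g_a,g_leak Maximal conductances (mS/cm^2).
#' @param sk_k_half SK calcium half-activation (uM) at `phi = 0`.
#' @param sk_hill SK Hill coefficient.
#' @param phi CaM-phosphorylation factor in `[0, 1]`.
#' @param ca_gain Calcium influx scale (uM per uA/cm^2 per ms).
#' @param ca_tau Calcium pool decay time constant (ms).
#' @param ca_rest Resting calcium (uM).
#' @param tau_a_inact A-current inactivation time constant (ms).
#' @param e_leak Leak reversal (mV); the depolarizing pacemaker drive.
#' @param noise_pA OU current noise amplitude (pA, stationary sd).
#' @param noise_tau_ms OU correlation time (ms).
#' @param area_um2 Membrane area (um^2) converting pA to uA/cm^2.
#' @param dt Integration step (ms, must be <= 0.05).
#' @param duration_s Simulated duration (s).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(g_na = 40, g_k = 6, g_ca = 0.3, g_sk = 3.5,
                       g_a = 1.5, g_leak = 0.05,
                       sk_k_half = 0.5, sk_hill = 4, phi = 0,
                       ca_gain = 0.006, ca_tau = 250, ca_rest = 0.05,
                       tau_a_inact = 150, e_leak = -30,
                       noise_pA = 40, noise_tau_ms = 5, area_um2 = 3000,
                       dt = 0.025, duration_s = 10, seed = 1L) {
  g <- c(g_na = g_na, g_k = g_k, g_ca = g_ca, g_sk = g_sk, g_a = g_a,
         g_leak = g_leak)
  if (any(g < 0)) stop("sim_params: conductances must be >= 0")
  if (phi < 0 || phi > 1) stop("sim_params: phi must lie in [0, 1]")
  if (dt <= 0 || dt > 0.05) stop("sim_params: dt must be in (0, 0.05] ms")
  if (duration_s <= 0) stop("sim_params: duration_s must be positive")
  structure(list(g_na = g_na, g_k = g_k, g_ca = g_ca, g_sk = g_sk,
                 g_a = g_a, g_leak = g_leak, sk_k_half = sk_k_half,
                 sk_hill = sk_hill, phi = phi, ca_gain = ca_gain,
                 ca_tau = ca_tau, ca_rest = ca_rest,
                 tau_a_inact = tau_a_inact, e_leak = e_leak,
                 noise_pA = noise_pA, noise_tau_ms = noise_tau_ms,
                 area_um2 = area_um2, dt = dt, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate spontaneous pacemaker firing
#'
#' Integrates the membrane model of [sim_params()] with a fixed-step
#' explicit method and returns the membrane-potential trace together with
#' the generator's ground truth (peak-based spike times, per-ISI voltage
#' minima, firing rate).  An optional square current step can be injected
#' for frequency-current protocols.
#'
#' @param params A [sim_params()] object.
#' @param step_pA Injected step amplitude (pA; 0 for none).
#' @param step_onset_s,step_duration_s Step timing (s).
#' @param discard_s Initial transient excluded from the ground-truth spike
#'   list (default 1 s; the full trace is still returned).
#' @return A list with elements `trace` (a voltage [trace()]) and
#'   `ground_truth` (list: `spike_times_s`, `rate_hz`, `isi_min_mV`,
#'   `params`).
#' @examples
#' \donttest{
#' sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 5))
#' sim$ground_truth$rate_hz
#' }
#' @export
simulate_pacemaker <- function(params, step_pA = 0, step_onset_s = 0,
                               step_duration_s = 0, discard_s = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  out <- .pacemaker_core(unclass(params), params$duration_s * 1000,
                         params$dt, step_pA, step_onset_s * 1000,
                         (step_onset_s + step_duration_s) * 1000, 1L)
  tr <- trace(out$V, dt = params$dt / 1000, signal = "voltage",
              mode = "whole_cell",
              meta = list(source = "simulate_pacemaker",
                          ljp_corrected = TRUE, g_sk = params$g_sk,
                          phi = params$phi, seed = params$seed))
  sp_all <- out$spike_ms / 1000
  sp <- sp_all[sp_all >= discard_s]
  span <- params$duration_s - discard_s
  isi_min <- if (length(sp_all) >= 2) {
    vapply(seq_len(length(sp_all) - 1L), function(i) {
      i0 <- floor(sp_all[i] * 1000 / params$dt) + 1L
      i1 <- floor(sp_all[i + 1L] * 1000 / params$dt) + 1L
      min(out$V[i0:i1])
    }, numeric(1))
  } else numeric(0)
  list(trace = tr,
       ground_truth = list(spike_times_s = sp,
                           spike_times_all_s = sp_all,
                           rate_hz = length(sp) / span,
                           isi_min_mV = isi_min,
                           params = params))
}

#' Simulate a frequency-current protocol
#'
#' Runs [simulate_pacemaker()] once per current step and returns the
#' voltage sweeps as a [sweep_set()] plus the ground-truth spike counts
#' during each step.
#'
#' @param params A [sim_params()]; `duration_s` is overridden to cover the
#'   step plus padding.
#' @param steps_pA Vector of step amplitudes (pA).
#' @param step_onset_s Step onset within each sweep (s).
#' @param step_duration_s Step length (s, default 1).
#' @return A list with `sweeps` (a [sweep_set()]) and `ground_truth`
#'   (data frame of step and spike count during the step).
#' @export
simulate_fi_sweeps <- function(params, steps_pA = seq(0, 250, by = 50),
                               step_onset_s = 0.5, step_duration_s = 1) {
  stopifnot(inherits(params, "sim_params"))
  span <- step_onset_s + step_duration_s + 0.25
  sweeps <- vector("list", length(steps_pA))
  counts <- integer(length(steps_pA))
  for (i in seq_along(steps_pA)) {
    p <- params
    p$duration_s <- span
    p$seed <- params$seed + i - 1L
    sim <- simulate_pacemaker(p, step_pA = steps_pA[i],
                              step_onset_s = step_onset_s,
                              step_duration_s = step_duration_s,
                              discard_s = 0)
    sweeps[[i]] <- sim$trace
    st <- sim$ground_truth$spike_times_all_s
    counts[i] <- sum(st >= step_onset_s & st < step_onset_s + step_duration_s)
  }
  list(sweeps = sweep_set(sweeps, holding = 0, step = steps_pA,
                          onset_s = step_onset_s,
                          duration_s = step_duration_s, step_units = "pA"),
       ground_truth = data.frame(step_pA = steps_pA, n_spikes = counts))
}

#' Simulate voltage-clamp protocol sweeps
#'
#' Phenomenological generators for the two voltage-clamp fixtures:
#' `simulate_tail_protocol()` emits current sweeps with a flat baseline, a
#' command-step plateau, and a mono-exponential decay tail after step
#' offset (the SK deactivation tail); `simulate_a_current_protocol()`
#' emits a bi-exponential inactivating outward transient from step onset.
#' Exact generating parameters, including the closed-form tail charge
#' `A * tau * (1 - exp(-T/tau))` over the integration window, are recorded
#' as ground truth.  Gaussian sample noise is seeded and reproducible.
#'
#' @param n_sweeps Number of identical sweeps.
#' @param amp_pA Tail amplitude at step offset (pA, outward positive).
#' @param tau_ms Tail decay time constant (ms).
#' @param holding_mV,step_mV Command levels (mV).
#' @param onset_s,duration_s Step timing (s).
#' @param span_s Total sweep length (s).
#' @param baseline_pA Holding current baseline (pA).
#' @param plateau_pA Current level during the step (pA; not analyzed).
#' @param noise_pA Gaussian noise sd (pA).
#' @param tail_window_ms Window for the recorded ground-truth charge (ms).
#' @param dt Sample interval (s).
#' @param seed Integer seed.
#' @return A list with `sweeps` (a [sweep_set()]) and `ground_truth`.
#' @export
simulate_tail_protocol <- function(n_sweeps = 3, amp_pA = 300, tau_ms = 100,
                                   holding_mV = -72, step_mV = -17,
                                   onset_s = 0.2, duration_s = 0.1,
                                   span_s = 1.6, baseline_pA = 0,
                                   plateau_pA = 150, noise_pA = 0,
                                   tail_window_ms = 1000, dt = 5e-5,
                                   seed = 1L) {
  stopifnot(tau_ms > 0)
  set.seed(seed)
  tt <- seq(0, span_s, by = dt)
  offset <- onset_s + duration_s
  base <- rep(baseline_pA, length(tt))
  base[tt >= onset_s & tt < offset] <- baseline_pA + plateau_pA
  post <- tt >= offset
  base[post] <- baseline_pA + amp_pA * exp(-(tt[post] - offset) * 1000 / tau_ms)
  sweeps <- lapply(seq_len(n_sweeps), function(i)
    trace(base + if (noise_pA > 0) rnorm(length(tt), 0, noise_pA) else 0,
          dt = dt, signal = "current", mode = "whole_cell",
          meta = list(source = "simulate_tail_protocol", sweep = i)))
  Tw <- tail_window_ms
  auc_pC <- amp_pA * (tau_ms / 1000) * (1 - exp(-Tw / tau_ms))
  list(sweeps = sweep_set(sweeps, holding = holding_mV, step = step_mV,
                          onset_s = onset_s, duration_s = duration_s,
                          step_units = "mV"),
       ground_truth = list(amp_pA = amp_pA, tau_ms = tau_ms,
                           auc_pC = auc_pC, window_ms = Tw,
                           baseline_pA = baseline_pA, seed = seed))
}

#' @rdname simulate_tail_protocol
#' @param a1_pA,tau1_ms,a2_pA,tau2_ms Bi-exponential amplitudes (pA) and
#'   time constants (ms) of the inactivating transient.
#' @param offset_pA Steady-state (non-inactivating) current (pA).
#' @export
simulate_a_current_protocol <- function(n_sweeps = 1, a1_pA = 400,
                                        tau1_ms = 50, a2_pA = 200,
                                        tau2_ms = 300, offset_pA = 20,
                                        holding_mV = -100, step_mV = -40,
                                        onset_s = 0.1, duration_s = 1,
                                        span_s = 1.2, noise_pA = 0,
                                        dt = 5e-5, seed = 1L) {
  stopifnot(tau1_ms > 0, tau2_ms > 0)
  set.seed(seed)
  tt <- seq(0, span_s, by = dt)
  cur <- rep(0, length(tt))
  on <- tt >= onset_s
  ts <- (tt[on] - onset_s) * 1000
  cur[on] <- offset_pA + a1_pA * exp(-ts / tau1_ms) + a2_pA * exp(-ts / tau2_ms)
  sweeps <- lapply(seq_len(n_sweeps), function(i)
    trace(cur + if (noise_pA > 0) rnorm(length(tt), 0, noise_pA) else 0,
          dt = dt, signal = "current", mode = "whole_cell",
          meta = list(source = "simulate_a_current_protocol", sweep = i)))
  list(sweeps = sweep_set(sweeps, holding = holding_mV, step = step_mV,
                          onset_s = onset_s, duration_s = duration_s,
                          step_units = "mV"),
       ground_truth = list(a1_pA = a1_pA, tau1_ms = tau1_ms, a2_pA = a2_pA,
                           tau2_ms = tau2_ms, offset_pA = offset_pA,
                           onset_s = onset_s, seed = seed))
}
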