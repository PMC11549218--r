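test_that("threshold-crossing spike detection follows its sign and level contract", {
  sq <- square_trace(n_cross = 2)
  sp <- detect_spikes(sq, threshold_mV = -10)
  expect_length(sp$times_s, 2)
  # events at the crossing samples of the square wave
  v <- sq$samples
  idx <- which(v[-1] >= -10 & v[-length(v)] < -10) + 1L
  expect_equal(sp$times_s, (idx - 1) * sq$dt)

  sine <- trace(-40 + 20 * sin(seq(0, 20 * pi, length.out = 5000)),
                dt = 1e-4, signal = "voltage", meta = list(ljp_corrected = TRUE))
  expect_warning(sp0 <- detect_spikes(sine, -10), "threshold above")
  expect_length(sp0$times_s, 0)
})

test_that("detected spike times match the simulator's peak ground truth within 1 ms", {
  sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 6))
  det <- detect_spikes(sim$trace)$times_s
  gt <- sim$ground_truth$spike_times_all_s
  expect_equal(length(det), length(gt))
  expect_lt(max(abs(det - gt)), 1e-3)
})

test_that("action-current detection recovers planted events and ignores polarity inversions", {
  times <- seq(0.2, 1.8, by = 0.25)
  tr <- planted_action_currents(times, amp_pA = -50, noise_pA = 2)
  sp <- detect_action_currents(tr)
  expect_length(sp$times_s, length(times))          # 100% recall & precision
  expect_lt(max(abs(sp$times_s - times)), 1e-3)

  flat <- trace(rep(0, 40001), dt = 5e-5, signal = "current",
                mode = "cell_attached")
  expect_length(detect_action_currents(flat)$times_s, 0)

  inv <- tr; inv$samples <- -inv$samples            # positive-going events
  expect_length(detect_action_currents(inv, threshold_pA = 25)$times_s, 0)
})

test_that("firing statistics follow the binned-rate and segment-CV definitions", {
  periodic <- spike_train(seq(0.25, 59.75, by = 0.5), span_s = 60)
  fs <- firing_stats(periodic)
  expect_equal(fs$rate_hz, 2, tolerance = 1e-6)
  expect_equal(fs$cv_isi, 0)

  two <- firing_stats(spike_train(c(1, 2), span_s = 10))
  expect_false(two$cv_defined)
  expect_true(is.na(two$cv_isi))

  set.seed(4)
  pois <- spike_train(sort(runif(1200, 0, 600)), span_s = 600)
  expect_equal(firing_stats(pois)$cv_isi, 1, tolerance = 0.1)
})

test_that("CV is invariant to uniform time rescaling while rate scales inversely", {
  set.seed(8)
  st <- cumsum(rexp(100, 3))
  a <- firing_stats(spike_train(st, span_s = max(st)))
  b <- firing_stats(spike_train(st * 2, span_s = max(st) * 2),
                    cv_segment_s = 20)
  expect_equal(b$cv_isi, a$cv_isi, tolerance = 1e-10)
  expect_equal(b$rate_hz, a$rate_hz / 2, tolerance = 0.05)
})

test_that("detection commutes with time shifts", {
  sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 3))
  k <- 400   # shift by k samples
  shifted <- trace(c(rep(sim$trace$samples[1], k), sim$trace$samples),
                   dt = sim$trace$dt, signal = "voltage",
                   meta = list(ljp_corrected = TRUE))
  t0 <- detect_spikes(sim$trace)$times_s
  t1 <- detect_spikes(shifted)$times_s
  expect_equal(t1, t0 + k * sim$trace$dt, tolerance = 1e-12)
})

test_that("apparent threshold honours the dV/dt criterion on a forced two-slope rise", {
  dt <- 1e-5
  seg1 <- seq(-60, -45, by = 5 * dt * 1000)        # 5 mV/ms
  seg2 <- seq(-45, 20, by = 20 * dt * 1000)        # 20 mV/ms
  down <- seq(20, -60, by = -20 * dt * 1000)
  v <- c(rep(-60, 3000), seg1, seg2, down, rep(-60, 3000))
  tr <- trace(v, dt = dt, signal = "voltage", meta = list(ljp_corrected = TRUE))
  sp <- detect_spikes(tr)
  wf <- spike_waveform_features(tr, sp)
  expect_equal(wf$threshold_mV, -45, tolerance = 0.3)
})

test_that("spike width equals the closed-form FWHM of a Gaussian spike", {
  dt <- 1e-5; sigma_ms <- 0.5; A <- 70; base <- -60
  t_ms <- seq(-15, 15, by = dt * 1000)
  v <- base + A * exp(-t_ms^2 / (2 * sigma_ms^2))
  tr <- trace(v, dt = dt, signal = "voltage", meta = list(ljp_corrected = TRUE))
  wf <- spike_waveform_features(tr, detect_spikes(tr), window_ms = 12)
  # closed form under the same definitions: threshold where the rising
  # dV/dt first reaches 10 mV/ms, half level midway between it and the peak
  f <- function(t) A * (-t / sigma_ms^2) * exp(-t^2 / (2 * sigma_ms^2)) - 10
  t_star <- uniroot(f, c(-6, -2 * sigma_ms))$root
  v_thr <- A * exp(-t_star^2 / (2 * sigma_ms^2))
  half_amp <- (v_thr + A) / 2
  expected <- 2 * sigma_ms * sqrt(2 * log(A / half_amp))
  expect_equal(wf$width_ms, expected, tolerance = 0.02)
  expect_equal(expected, 2.355 * sigma_ms, tolerance = 0.05)
  expect_equal(wf$threshold_mV, base + v_thr, tolerance = 0.2)
})

test_that("threshold is stable under halving the integration step", {
  f <- function(dt) {
    sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 4, dt = dt))
    spike_waveform_features(sim$trace, detect_spikes(sim$trace))$threshold_mV
  }
  expect_lt(abs(f(0.025) - f(0.0125)), 0.5)
})

test_that("ISI trajectories reproduce closed forms and resampling identities", {
  tr <- linear_isi_trace()
  sp <- spike_train(c(0, 0.2), span_s = trace_span(tr))
  tj <- isi_voltage_trajectory(tr, sp)
  expect_equal(ncol(tj$rows), 1000)
  expect_equal(tj$min_mV, -60)
  expect_equal(tj$min_time_ms, 0)
  expect_equal(tj$mahp_mV, -32.5, tolerance = 1e-9)
  expect_false(tj$mahp_truncated)

  # two identical ISIs (periodic sawtooth): the average equals either row
  ramp <- tr$samples[1:2000]            # [0, 200) ms, right-open
  tr2 <- trace(c(ramp, ramp, -60), dt = tr$dt, signal = "voltage",
               meta = list(ljp_corrected = TRUE))
  sp2 <- spike_train(c(0, 0.2, 0.4), span_s = trace_span(tr2))
  tj2 <- isi_voltage_trajectory(tr2, sp2)
  expect_equal(tj2$rows[1, ], tj2$rows[2, ], tolerance = 1e-9)
  expect_equal(tj2$average, tj2$rows[1, ], tolerance = 1e-9)

  # resampling a 1000-sample ISI reproduces the input on the same grid
  set.seed(2)
  v <- -60 + cumsum(rnorm(1001, 0, 0.1))
  tr3 <- trace(v, dt = 1e-3, signal = "voltage",
               meta = list(ljp_corrected = TRUE))
  sp3 <- spike_train(c(0, 1), span_s = 1)
  tj3 <- isi_voltage_trajectory(tr3, sp3)
  expect_equal(as.numeric(tj3$rows[1, ]), v[1:1000], tolerance = 1e-6)

  # an ISI shorter than the mAHP window is flagged truncated
  trs <- linear_isi_trace(isi_ms = 80)
  tjs <- isi_voltage_trajectory(trs, spike_train(c(0, 0.08),
                                                 span_s = trace_span(trs)))
  expect_true(tjs$mahp_truncated)
})

test_that("cell_features applies the junction correction exactly once", {
  sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 4))
  raw <- sim$trace
  raw$meta$ljp_corrected <- NULL   # pretend this is an uncorrected recording
  cfg <- default_config()
  feats_raw <- cell_features(raw, cfg)
  feats_cor <- cell_features(sim$trace, cfg)
  # one-sample detection offsets shift the resampling grid slightly
  expect_equal(feats_raw$min_isi_mV,
               feats_cor$min_isi_mV + cfg$ljp$vj_whole_cell,
               tolerance = 1e-4)
  expect_equal(feats_raw$rate_hz, feats_cor$rate_hz, tolerance = 0.2)
})
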