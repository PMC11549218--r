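test_that("tail metrics recover rectangle and exponential closed forms", {
  # rectangle: 100 pA above baseline for exactly 100 ms after offset
  dt <- 5e-5
  tt <- seq(0, 1, by = dt)
  cur <- ifelse(tt >= 0.3 & tt < 0.4, 100, 0)
  sw <- sweep_set(list(trace(cur, dt, signal = "current")),
                  holding = -72, step = -17, onset_s = 0.2, duration_s = 0.1)
  tm <- tail_current_metrics(sw)
  expect_equal(tm$amplitude_pA, 100)
  expect_equal(tm$auc_pC, 10, tolerance = 1e-2)

  tp <- simulate_tail_protocol(amp_pA = 300, tau_ms = 100, noise_pA = 0,
                               span_s = 1.6)
  tm2 <- tail_current_metrics(tp$sweeps, window_ms = 1000, recross_ms = 1e6)
  analytic <- 300 * 0.1 * (1 - exp(-10))
  expect_lt(abs(tm2$auc_pC - analytic) / analytic, 0.001)
  expect_equal(tm2$amplitude_pA, 300, tolerance = 1)
})

test_that("an apamin-like 3x generator reduction shows up as a 3x measured amplitude", {
  hi <- simulate_tail_protocol(amp_pA = 300, noise_pA = 3, seed = 1)
  lo <- simulate_tail_protocol(amp_pA = 100, noise_pA = 3, seed = 2)
  r <- tail_current_metrics(hi$sweeps)$amplitude_pA /
    tail_current_metrics(lo$sweeps)$amplitude_pA
  expect_equal(r, 3, tolerance = 0.1)
})

test_that("F-I gain is the least-squares slope over 0-60 pA and is order-invariant", {
  # sweeps with planted spike counts: n brief suprathreshold pulses each
  mk <- function(n_spikes, dt = 1e-4, onset = 0.2, dur = 1) {
    v <- rep(-60, round((onset + dur + 0.2) / dt))
    if (n_spikes > 0) {
      at <- onset + (seq_len(n_spikes) - 0.5) / n_spikes * dur
      for (t0 in at) v[round(t0 / dt) + 0:3] <- 10
    }
    trace(v, dt, signal = "voltage", meta = list(ljp_corrected = TRUE))
  }
  sw <- sweep_set(list(mk(0), mk(3), mk(6)), holding = 0,
                  step = c(0, 30, 60), onset_s = 0.2, duration_s = 1,
                  step_units = "pA")
  fi <- fi_gain(sw)
  expect_equal(fi$gain_hz_per_pA, 0.1, tolerance = 1e-9)

  perm <- sweep_set(list(mk(6), mk(0), mk(3)), holding = 0,
                    step = c(60, 0, 30), onset_s = 0.2, duration_s = 1,
                    step_units = "pA")
  expect_equal(fi_gain(perm)$gain_hz_per_pA, fi$gain_hz_per_pA)

  zero <- sweep_set(list(mk(0), mk(0), mk(0)), holding = 0,
                    step = c(0, 30, 60), onset_s = 0.2, duration_s = 1,
                    step_units = "pA")
  expect_equal(fi_gain(zero)$gain_hz_per_pA, 0)

  two <- sweep_set(list(mk(0), mk(3)), holding = 0, step = c(0, 30),
                   onset_s = 0.2, duration_s = 1, step_units = "pA")
  expect_false(fi_gain(two)$gain_defined)
})

test_that("bi-exponential inactivation fits recover generating parameters", {
  ap <- simulate_a_current_protocol(a1_pA = 400, tau1_ms = 50, a2_pA = 200,
                                    tau2_ms = 300, noise_pA = 0)
  fit <- a_current_inactivation(ap$sweeps$sweeps[[1]])
  expect_lt(abs(fit$tau1_ms - 50) / 50, 0.01)
  expect_lt(abs(fit$tau2_ms - 300) / 300, 0.01)
  expect_false(fit$degenerate)
  expect_gt(fit$r_squared, 0.999)

  mono <- simulate_a_current_protocol(a1_pA = 400, tau1_ms = 80, a2_pA = 0,
                                      tau2_ms = 80, noise_pA = 0)
  mfit <- a_current_inactivation(mono$sweeps$sweeps[[1]])
  expect_true(mfit$degenerate)

  errs <- vapply(1:5, function(s) {
    no <- simulate_a_current_protocol(noise_pA = 5, seed = s)
    f <- a_current_inactivation(no$sweeps$sweeps[[1]])
    max(abs(f$tau1_ms - 50) / 50, abs(f$tau2_ms - 300) / 300)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("rebound delay measures offset-to-first-spike and returns the none sentinel", {
  dt <- 1e-4
  v <- rep(-80, 30000)
  v[round(1.3 / dt) + 0:3] <- 10     # spike 300 ms after offset at 1.0 s
  tr <- trace(v, dt, signal = "voltage", meta = list(ljp_corrected = TRUE))
  expect_equal(rebound_delay(tr, step_offset_s = 1), 300, tolerance = 0.5)
  silent <- trace(rep(-80, 30000), dt, signal = "voltage",
                  meta = list(ljp_corrected = TRUE))
  expect_true(is.na(rebound_delay(silent, step_offset_s = 1)))
})

test_that("EPSC charge integrates with sign and matches the alpha-function closed form", {
  dt <- 5e-5
  tt <- seq(0, 0.5, by = dt)
  rect <- trace(ifelse(tt >= 0.2 & tt < 0.22, -50, 0), dt, signal = "current")
  expect_equal(epsc_charge(rect, c(0, 0.19), c(0.2, 0.25)), -1,
               tolerance = 5e-3)

  A <- -80; tau <- 0.005
  alpha <- ifelse(tt >= 0.1, A * ((tt - 0.1) / tau) * exp(1 - (tt - 0.1) / tau), 0)
  atr <- trace(alpha, dt, signal = "current")
  analytic <- A * exp(1) * tau  # integral of A*(t/tau)exp(1 - t/tau) over [0, Inf)
  got <- epsc_charge(atr, c(0, 0.09), c(0.1, 0.5))
  expect_lt(abs(got - analytic) / abs(analytic), 0.001)

  zero <- trace(rep(0, length(tt)), dt, signal = "current")
  expect_equal(epsc_charge(zero, c(0, 0.1), c(0.1, 0.4)), 0)
})

test_that("trapezoidal charge is exact for piecewise-linear input", {
  dt <- 1e-4
  tt <- seq(0, 0.2, by = dt)
  tri <- ifelse(tt >= 0.05 & tt <= 0.15, 100 * (1 - abs(tt - 0.1) / 0.05), 0)
  tr <- trace(tri, dt, signal = "current")
  # triangle area: 0.5 * base (0.1 s) * height (100 pA) = 5 pC
  expect_equal(epsc_charge(tr, c(0, 0.04), c(0.05, 0.15)), 5,
               tolerance = 1e-9)
})

test_that("cell classification follows the published rule sets", {
  vta <- classify_cell(rate_hz = 2, width_ms = 1.3, tau_a_ms = 150,
                       rebound_ms = 300, region = "VTA")
  expect_identical(vta$label, "VTA_DA")

  snc <- classify_cell(rate_hz = 3, width_ms = 1.2, ih_pA = 250,
                       region = "SNc")
  expect_identical(snc$label, "SNc_DA")

  expect_identical(classify_cell(rate_hz = 20, width_ms = 0.5)$label,
                   "unclassified")

  lc <- classify_cell(rate_hz = 1, width_ms = 0.8, tau_a_ms = 200,
                      rm_mohm = 60)
  expect_identical(lc$label, "LC_NE")

  # missing features fail closed without a region hint
  expect_identical(classify_cell(rate_hz = 2, width_ms = 1.3)$label,
                   "unclassified")

  # the decision is reproducible from the rule trace
  expect_true(all(c("rule", "check", "value", "result") %in%
                    names(vta$rule_trace)))
  expect_true(all(vta$rule_trace$result[vta$rule_trace$rule == "VTA_DA"] ==
                    "pass"))
  again <- classify_cell(rate_hz = 2, width_ms = 1.3, tau_a_ms = 150,
                         rebound_ms = 300, region = "VTA")
  expect_identical(again$rule_trace, vta$rule_trace)
})
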