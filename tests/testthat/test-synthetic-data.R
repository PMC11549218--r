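test_that("noise-free pacemaking is a limit cycle in the published rate band", {
  sim <- simulate_pacemaker(sim_params(noise_pA = 0, duration_s = 6))
  gt <- sim$ground_truth
  expect_gt(length(gt$spike_times_s), 3)
  isi <- diff(gt$spike_times_s)
  expect_lt(sd(isi) / mean(isi), 0.01)
  expect_gt(gt$rate_hz, 0.5)
  expect_lt(gt$rate_hz, 4)
})

test_that("default parameters fire inside 0.5-4 Hz across a 10-seed ensemble", {
  rates <- vapply(1:10, function(s)
    simulate_pacemaker(sim_params(duration_s = 5, seed = s))$ground_truth$rate_hz,
    numeric(1))
  expect_gt(mean(rates), 0.5)
  expect_lt(mean(rates), 4)
})

test_that("reducing g_SK speeds firing and depolarizes ISI minima (matched seeds)", {
  for (s in 1:3) {
    wt <- simulate_pacemaker(sim_params(duration_s = 8, seed = s))
    lo <- simulate_pacemaker(sim_params(g_sk = 3.5 * 0.4, duration_s = 8,
                                        seed = s))
    expect_gt(lo$ground_truth$rate_hz, wt$ground_truth$rate_hz)
    expect_gt(mean(lo$ground_truth$isi_min_mV),
              mean(wt$ground_truth$isi_min_mV))
  }
})

test_that("ensemble mean rate is monotone in g_SK and in phi", {
  mean_rate <- function(...) mean(vapply(1:6, function(s)
    simulate_pacemaker(sim_params(..., duration_s = 4,
                                  seed = s))$ground_truth$rate_hz,
    numeric(1)))
  r_gsk <- vapply(c(0.5, 2, 4), function(g) mean_rate(g_sk = g), numeric(1))
  expect_true(all(diff(r_gsk) <= 0))
  r_phi <- vapply(c(0, 0.5, 1), function(ph) mean_rate(phi = ph), numeric(1))
  expect_true(all(diff(r_phi) >= 0))
})

test_that("simulator rejects invalid parameters and numerical blow-up", {
  expect_error(sim_params(g_na = -1), "conductances")
  expect_error(sim_params(phi = 1.5), "phi")
  expect_error(sim_params(dt = 0.1), "dt")
  expect_error(
    simulate_pacemaker(sim_params(g_na = 5000, g_k = 0, dt = 0.05,
                                  duration_s = 1, noise_pA = 0)),
    "diverged")
})

test_that("voltage-clamp generators record exact ground truth and are seeded", {
  tp <- simulate_tail_protocol(amp_pA = 300, tau_ms = 100, noise_pA = 0,
                               tail_window_ms = 1000)
  expect_equal(tp$ground_truth$auc_pC,
               300 * 0.1 * (1 - exp(-10)), tolerance = 1e-12)
  ap <- simulate_a_current_protocol(a1_pA = 400, tau1_ms = 50, a2_pA = 200,
                                    tau2_ms = 300)
  expect_equal(ap$ground_truth[c("tau1_ms", "tau2_ms")],
               list(tau1_ms = 50, tau2_ms = 300))
  n1 <- simulate_tail_protocol(noise_pA = 5, seed = 42)
  n2 <- simulate_tail_protocol(noise_pA = 5, seed = 42)
  expect_identical(n1$sweeps$sweeps[[1]]$samples,
                   n2$sweeps$sweeps[[1]]$samples)
})

test_that("synthetic Patch-seq counts are reproducible, integer and marker-structured", {
  a <- synth_patchseq(n_genes = 200, seed = 3)
  b <- synth_patchseq(n_genes = 200, seed = 3)
  expect_identical(a$matrix$counts, b$matrix$counts)
  cts <- a$matrix$counts
  expect_true(all(cts >= 0) && all(cts == round(cts)))
  expect_true(all(cts[c("Th", "Slc6a3", "Slc18a2"), ] >= 1))
  contam <- colnames(cts) %in% a$ground_truth$contaminated_cells
  expect_true(all(colSums(cts[a$ground_truth$negative_markers,
                              !contam, drop = FALSE]) == 0))
  expect_true(all(colSums(cts[a$ground_truth$negative_markers,
                              contam, drop = FALSE]) > 0))
})

test_that("a strongly planted gene-covariate correlation survives counting noise", {
  out <- synth_patchseq(n_genes = 100, n_cells_per_group = c(34, 34),
                        deg_fraction = 0, corr_genes = 1, corr_r = 0.99,
                        contam_fraction = 0, seed = 5)
  g <- out$ground_truth$corr$gene[1]
  r <- cor(out$matrix$counts[g, ] / out$ground_truth$size_factors,
           out$matrix$covariates$tail_pA)
  expect_gt(r, 0.9)
})

test_that("behavior generator honours planted acquisition days and seeds", {
  out <- synth_behavior(n_mice = 6, learner_fraction = 0.5, seed = 9)
  gt <- out$ground_truth
  for (m in seq_along(out$mice)) {
    acc <- vapply(out$mice[[m]]$daily_logs, session_accuracy, numeric(1))
    if (is.na(gt$acquisition_day[m])) {
      expect_true(all(acc < 70))
    } else {
      expect_identical(acquisition_day(acc), gt$acquisition_day[m])
    }
  }
  out2 <- synth_behavior(n_mice = 6, learner_fraction = 0.5, seed = 9)
  expect_identical(out$mice[[1]]$daily_logs[[1]],
                   out2$mice[[1]]$daily_logs[[1]])
  expect_identical(out$mice[[3]]$path, out2$mice[[3]]$path)
})
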