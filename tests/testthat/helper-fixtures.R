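# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except through the package's own writers.

# voltage trace that linearly ramps between spikes (worked-example fixture)
linear_isi_trace <- function(isi_ms = 200, v0 = -60, slope = 0.5, dt = 1e-4) {
  t_ms <- seq(0, isi_ms, by = dt * 1000)
  trace(v0 + slope * t_ms, dt = dt, signal = "voltage",
        meta = list(ljp_corrected = TRUE))
}

# square-wave voltage trace crossing a level a known number of times
square_trace <- function(n_cross = 2, lo = -60, hi = 0, half_ms = 50,
                         dt = 1e-4) {
  half_n <- round(half_ms / 1000 / dt)
  v <- rep(rep(c(lo, hi), n_cross), each = half_n)
  trace(c(rep(lo, half_n), v), dt = dt, signal = "voltage",
        meta = list(ljp_corrected = TRUE))
}

# cell-attached current trace with planted biphasic action-current events
planted_action_currents <- function(event_times_s, amp_pA = -50,
                                    span_s = 2, dt = 5e-5, noise_pA = 2,
                                    seed = 1) {
  set.seed(seed)
  n <- round(span_s / dt) + 1
  cur <- rnorm(n, 0, noise_pA)
  # biphasic template: sharp negative lobe then smaller positive lobe
  t_ms <- seq(0, 4, by = dt * 1000)
  tmpl <- amp_pA * exp(-((t_ms - 1) / 0.4)^2) -
    0.35 * amp_pA * exp(-((t_ms - 2.2) / 0.7)^2)
  for (te in event_times_s) {
    i0 <- round(te / dt) + 1 - round(0.001 / dt)  # negative peak at te
    idx <- i0 + seq_along(tmpl) - 1
    ok <- idx >= 1 & idx <= n
    cur[idx[ok]] <- cur[idx[ok]] + tmpl[ok]
  }
  trace(cur, dt = dt, signal = "current", mode = "cell_attached")
}

# independent Henderson evaluation by numerical quadrature of the junction
# integral along the linear mixing path (oracle for the closed form)
quadrature_ljp <- function(pipette, bath, temperature_K = 298.15, n = 20001) {
  m <- skpatch:::merge_solutions(pipette, bath)
  RTF <- 1000 * 8.314462618 * temperature_K / 96485.33212
  x <- seq(0, 1, length.out = n)
  num <- den <- numeric(n)
  u <- m$lambda / abs(m$z)              # mobility per unit charge
  dcdx <- m$cB - m$cP
  for (i in seq_len(n)) {
    ci <- m$cP + x[i] * dcdx
    num[i] <- sum(m$z * u * dcdx)
    den[i] <- sum(m$z^2 * u * ci)
  }
  dphi <- -RTF * num / den
  phiB_minus_phiP <- pracma::trapz(x, dphi)
  -phiB_minus_phiP
}

# brute-force BH by the textbook definition: sort, scale, cummin, unsort
brute_bh <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  scaled <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  res <- rep(NA_real_, length(p))
  res[ok][o] <- adj
  res
}

# brute-force two-sample KS D as the sup of |ECDF_a - ECDF_b|
brute_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

# small hand-enumerable QC matrix: 5 cells, one Pvalb+ and one Th-
toy_qc_matrix <- function() {
  genes <- c("Th", "Slc6a3", "Slc18a2", "Pvalb", "Tmem119", "P2ry12",
             "Aldh1l1", "Actb")
  counts <- rbind(
    Th      = c(5, 4, 0, 6, 3),
    Slc6a3  = c(3, 2, 2, 5, 4),
    Slc18a2 = c(2, 6, 3, 4, 2),
    Pvalb   = c(0, 0, 0, 7, 0),
    Tmem119 = c(0, 0, 0, 0, 0),
    P2ry12  = c(0, 0, 0, 0, 0),
    Aldh1l1 = c(0, 0, 0, 0, 0),
    Actb    = c(9, 9, 9, 9, 9))
  colnames(counts) <- paste0("c", 1:5)
  count_matrix(counts, rep(c("WT", "3xTg"), c(3, 2)))
}
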