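#' Synthesize a Patch-seq count matrix with planted ground truth
#'
#' Negative-binomial counts with log-normal per-cell size factors,
#' emulating the statistical structure of a two-group Patch-seq
#' experiment.  Positive dopamine-neuron markers (`Th`, `Slc6a3`,
#' `Slc18a2`) are expressed in every clean cell; a configurable fraction
#' of cells is "contaminated" and additionally expresses the negative
#' markers (`Pvalb`, `Tmem119`, `P2ry12`, `Aldh1l1`), so the generated
#' data exercises the QC filter.  A fraction of genes is differentially
#' expressed between the groups at the stated fold change (half up, half
#' down), and a set of genes tracks a per-cell tail-current amplitude
#' covariate with latent Pearson correlation `corr_r` (counts are kept
#' high-mean and low-dispersion for those genes so the realized sample
#' correlation stays close to the planted value).
#'
#' @param n_genes Background genes (markers are added on top).
#' @param n_cells_per_group Length-2 integer vector.
#' @param deg_fraction Fraction of background genes planted as DEGs.
#' @param fold_change Planted fold change (> 1).
#' @param corr_genes Number of covariate-tracking genes.
#' @param corr_r Planted latent Pearson correlation (|r| < 1).
#' @param contam_fraction Fraction of contaminated cells per group.
#' @param base_meanlog,base_sdlog Log-normal background gene mean
#'   distribution.
#' @param nb_size Negative-binomial size (inverse dispersion) of
#'   background genes.
#' @param sf_sdlog Log-normal size-factor spread.
#' @param group_labels Two group names.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `matrix` (a [count_matrix()] whose covariates
#'   carry `tail_pA`) and `ground_truth` (planted DEG table, correlated
#'   genes, markers, contaminated cells, size factors).
#' @export
synth_patchseq <- function(n_genes = 2000, n_cells_per_group = c(30, 30),
                           deg_fraction = 0.025, fold_change = 2,
                           corr_genes = 5, corr_r = 0.6,
                           contam_fraction = 0.1,
                           base_meanlog = log(30), base_sdlog = 0.8,
                           nb_size = 5, sf_sdlog = 0.3,
                           group_labels = c("WT", "3xTg"), seed = 1L) {
  if (fold_change <= 1) stop("synth_patchseq: fold_change must be > 1")
  if (abs(corr_r) >= 1) stop("synth_patchseq: |corr_r| must be < 1")
  if (deg_fraction < 0 || deg_fraction > 1)
    stop("synth_patchseq: deg_fraction must lie in [0, 1]")
  set.seed(seed)
  n1 <- n_cells_per_group[1]; n2 <- n_cells_per_group[2]
  n_cells <- n1 + n2
  group <- factor(rep(group_labels, c(n1, n2)), levels = group_labels)
  cells <- sprintf("cell_%03d", seq_len(n_cells))

  pos_markers <- c("Th", "Slc6a3", "Slc18a2")
  neg_markers <- c("Pvalb", "Tmem119", "P2ry12", "Aldh1l1")
  bg_genes <- sprintf("gene_%04d", seq_len(n_genes))
  genes <- c(pos_markers, neg_markers, bg_genes)

  sf <- rlnorm(n_cells, 0, sf_sdlog)
  tail_pA <- pmax(20, rnorm(n_cells, mean = 250, sd = 60))
  z_tail <- as.numeric(scale(tail_pA))

  n_deg <- round(deg_fraction * n_genes)
  deg_idx <- seq_len(n_deg)
  corr_idx <- n_deg + seq_len(corr_genes)
  if (n_deg + corr_genes > n_genes)
    stop("synth_patchseq: not enough background genes for DEGs + correlated genes")

  base_mean <- rlnorm(n_genes, base_meanlog, base_sdlog)
  mu <- matrix(base_mean, n_genes, n_cells)
  deg_dir <- rep(c(1, -1), length.out = n_deg)
  for (k in seq_along(deg_idx)) {
    fac <- if (deg_dir[k] > 0) fold_change else 1 / fold_change
    mu[deg_idx[k], group == group_labels[2]] <-
      mu[deg_idx[k], group == group_labels[2]] * fac
  }
  # covariate-tracking genes: high-mean linear signal plus small residual
  corr_mu0 <- 500; corr_sig <- 100
  for (k in seq_along(corr_idx)) {
    eps <- rnorm(n_cells)
    lat <- corr_r * z_tail + sqrt(1 - corr_r^2) * eps
    mu[corr_idx[k], ] <- pmax(5, corr_mu0 + corr_sig * lat)
  }
  mu <- sweep(mu, 2, sf, "*")
  size_mat <- matrix(nb_size, n_genes, n_cells)
  size_mat[corr_idx, ] <- 500           # low biological dispersion for planted r
  bg_counts <- matrix(rnbinom(n_genes * n_cells, mu = as.vector(mu),
                              size = as.vector(size_mat)),
                      n_genes, n_cells)

  contam <- rep(FALSE, n_cells)
  for (g in group_labels) {
    idx <- which(group == g)
    n_c <- round(contam_fraction * length(idx))
    if (n_c > 0) contam[sample(idx, n_c)] <- TRUE
  }
  pos_counts <- matrix(rnbinom(3 * n_cells, mu = rep(200 * sf, each = 3),
                               size = 10), 3, n_cells)
  pos_counts[pos_counts == 0] <- 1      # markers present in every cell
  neg_counts <- matrix(0L, 4, n_cells)
  if (any(contam))
    neg_counts[, contam] <- matrix(
      rnbinom(4 * sum(contam), mu = rep(50 * sf[contam], each = 4), size = 5) + 1L,
      4, sum(contam))

  counts <- rbind(pos_counts, neg_counts, bg_counts)
  dimnames(counts) <- list(genes, cells)
  cm <- count_matrix(counts, group,
                     covariates = data.frame(tail_pA = tail_pA))
  gt <- list(
    deg = data.frame(gene = bg_genes[deg_idx],
                     fold_change = ifelse(deg_dir > 0, fold_change,
                                          1 / fold_change)),
    corr = data.frame(gene = bg_genes[corr_idx],
                      r = rep(corr_r, length(corr_idx))),
    positive_markers = pos_markers, negative_markers = neg_markers,
    contaminated_cells = cells[contam],
    size_factors = setNames(sf, cells),
    tail_pA = setNames(tail_pA, cells), seed = seed)
  list(matrix = cm, ground_truth = gt)
}
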