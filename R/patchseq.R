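#' Construct a gene-by-cell count matrix
#'
#' Integer counts with gene symbols as row names, cell ids as column
#' names, one group label per cell and optional per-cell physiology
#' covariates (e.g. tail-current amplitude) joined by cell id.
#'
#' @param counts Integer matrix (genes x cells) with dimnames.
#' @param group Factor or character, one label per cell.
#' @param covariates Optional data frame, one row per cell.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, group, covariates = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: counts need gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("count_matrix: gene symbols must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  if (length(group) != ncol(counts))
    stop("count_matrix: one group label per cell required")
  group <- as.factor(group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != ncol(counts))
      stop("count_matrix: covariates must have one row per cell")
    rownames(covariates) <- colnames(counts)
  }
  structure(list(counts = counts, group = group, covariates = covariates),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

subset_cells <- function(x, keep) {
  count_matrix(x$counts[, keep, drop = FALSE], x$group[keep],
               if (is.null(x$covariates)) NULL else
                 x$covariates[keep, , drop = FALSE])
}

#' Marker-based cell quality control
#'
#' Retains cells that express all positive dopamine-neuron markers (`Th`,
#' `Slc6a3`, `Slc18a2` by default) at or above `positive_min_count`
#' counts, and show at most `negative_max_count` counts for every
#' contamination marker (`Pvalb`, `Tmem119`, `P2ry12`, `Aldh1l1`:
#' interneuron, microglia, astrocyte markers).  Attrition per criterion
#' is attached as the `attrition` attribute.
#'
#' @param x A [count_matrix()].
#' @param positive_markers,negative_markers Marker gene sets.
#' @param positive_min_count Minimum count for each positive marker.
#' @param negative_max_count Maximum count for each negative marker.
#' @return The filtered [count_matrix()].
#' @export
qc_filter_cells <- function(x,
                            positive_markers = c("Th", "Slc6a3", "Slc18a2"),
                            negative_markers = c("Pvalb", "Tmem119",
                                                 "P2ry12", "Aldh1l1"),
                            positive_min_count = 1,
                            negative_max_count = 0) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(c(positive_markers, negative_markers), rownames(x$counts))
  if (length(missing))
    stop("qc_filter_cells: marker genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  pos_ok <- colSums(x$counts[positive_markers, , drop = FALSE] >=
                      positive_min_count) == length(positive_markers)
  neg_ok <- colSums(x$counts[negative_markers, , drop = FALSE] <=
                      negative_max_count) == length(negative_markers)
  keep <- pos_ok & neg_ok
  if (!any(keep))
    stop("qc_filter_cells: no cell passed; review marker thresholds")
  out <- subset_cells(x, keep)
  attr(out, "attrition") <- data.frame(
    criterion = c("input", "positive_markers", "negative_markers", "retained"),
    cells = c(ncol(x$counts), sum(pos_ok), sum(neg_ok), sum(keep)))
  out
}

#' Expression filter
#'
#' Keeps genes with at least `min_count` counts in at least
#' `min_fraction` of the cells of at least one group (the per-group
#' variant mirrors how sparsely expressed but group-specific transcripts
#' are retained).
#'
#' @param x A [count_matrix()].
#' @param min_count Count threshold per cell (default 1).
#' @param min_fraction Required fraction of cells (default 0.8).
#' @param per_group Evaluate the fraction within each group (default
#'   `TRUE`); otherwise across all cells.
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(x, min_count = 1, min_fraction = 0.8,
                             per_group = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  expressed <- x$counts >= min_count
  if (per_group) {
    if (nlevels(x$group) < 2)
      stop("filter_expressed: per_group = TRUE needs at least 2 groups")
    fr <- vapply(levels(x$group), function(g)
      rowMeans(expressed[, x$group == g, drop = FALSE]), numeric(nrow(x$counts)))
    keep <- apply(fr, 1, max) >= min_fraction
  } else {
    keep <- rowMeans(expressed) >= min_fraction
  }
  count_matrix(x$counts[keep, , drop = FALSE], x$group, x$covariates)
}

#' Median-of-ratios size-factor normalization
#'
#' Per-cell size factors are the median, over reference genes, of the
#' ratio of the cell's count to the gene's geometric mean across cells;
#' reference genes are those with nonzero counts in every cell.  Factors
#' are rescaled to geometric mean 1 and normalized values are counts
#' divided by the cell's factor.  When no gene is expressed in all cells
#' the geometric means fall back to positive counts only (with a
#' warning), keeping the estimator usable on sparse matrices.
#'
#' @param x A [count_matrix()].
#' @return A list of class `normalized_counts`: `normalized` (matrix),
#'   `size_factors`, `group`, `covariates`.
#' @export
size_factor_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  all_pos <- rowSums(cts == 0) == 0
  if (any(all_pos)) {
    ref <- cts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    sf <- apply(ref / geo, 2, median)
  } else {
    warning("size_factor_normalize: no all-nonzero gene; using positive counts only")
    lg <- log(cts)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ratios <- cts / geo
    ratios[cts == 0] <- NA
    sf <- apply(ratios, 2, median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("size_factor_normalize: undefined size factor")
  sf <- sf / exp(mean(log(sf)))
  structure(list(normalized = sweep(cts, 2, sf, "/"),
                 size_factors = sf, group = x$group,
                 covariates = x$covariates),
            class = "normalized_counts")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: p-values are ranked, scaled
#' by `m / rank`, and monotonicity is enforced by a cumulative minimum
#' from the largest p downward; ties share their adjusted value.  `NA`
#' entries propagate and are excluded from `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_adjust: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  out[ok] <- adj
  out
}

#' Per-gene differential expression between two groups
#'
#' Two-sample t-test (Welch by default) on normalized expression,
#' Benjamini-Hochberg adjustment, and a fold-change filter.  The fold
#' change is the ratio of group means (second group level over first)
#' with a pseudo-count guarding against division by zero; `abs_fc` is the
#' larger of the ratio and its reciprocal.  A gene is flagged as
#' differentially expressed when `fdr < fdr_cutoff` and `abs_fc >
#' fc_cutoff`, both strict.  Genes with zero variance in both groups get
#' `p = 1` and a flag.
#'
#' @param norm A [size_factor_normalize()] result (or a matrix plus
#'   `group`).
#' @param group Optional group factor when `norm` is a plain matrix.
#' @param fdr_cutoff FDR threshold (strict `<`, default 0.1).
#' @param fc_cutoff Absolute fold-change threshold (strict `>`, default 1.25).
#' @param pseudo_count Added to group means for the ratio (default 0.5).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A data frame of class `gene_stats` with one row per gene:
#'   `gene`, `mean_<group1>`, `mean_<group2>`, `fold_change`, `abs_fc`,
#'   `direction`, `p`, `fdr`, `deg`, `zero_variance`; the up/down counts
#'   are in `attr(, "summary")`.
#' @export
differential_expression <- function(norm, group = NULL, fdr_cutoff = 0.1,
                                    fc_cutoff = 1.25, pseudo_count = 0.5,
                                    var_equal = FALSE) {
  if (inherits(norm, "normalized_counts")) {
    mat <- norm$normalized
    group <- norm$group
  } else {
    mat <- as.matrix(norm)
    if (is.null(group)) stop("differential_expression: 'group' required")
    group <- as.factor(group)
  }
  if (nlevels(group) != 2)
    stop("differential_expression: exactly two groups required")
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  i1 <- group == g1; i2 <- group == g2
  if (sum(i1) < 3 || sum(i2) < 3)
    stop("differential_expression: need >= 3 cells per group")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1, var)
  v2 <- apply(mat[, i2, drop = FALSE], 1, var)
  zerovar <- v1 == 0 & v2 == 0
  p <- rep(1, nrow(mat))
  todo <- which(!zerovar)
  for (i in todo)
    p[i] <- t.test(mat[i, i1], mat[i, i2], var.equal = var_equal)$p.value
  fdr <- bh_adjust(p)
  fc <- (m2 + pseudo_count) / (m1 + pseudo_count)
  abs_fc <- pmax(fc, 1 / fc)
  out <- data.frame(gene = rownames(mat),
                    mean_1 = m1, mean_2 = m2,
                    fold_change = fc, abs_fc = abs_fc,
                    direction = ifelse(fc >= 1, "up", "down"),
                    p = p, fdr = fdr,
                    deg = fdr < fdr_cutoff & abs_fc > fc_cutoff,
                    zero_variance = zerovar,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", c(g1, g2))
  attr(out, "summary") <- list(
    n_genes = nrow(out), n_deg = sum(out$deg),
    n_up = sum(out$deg & out$direction == "up"),
    n_down = sum(out$deg & out$direction == "down"),
    fdr_cutoff = fdr_cutoff, fc_cutoff = fc_cutoff)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Correlate gene expression with a physiology covariate
#'
#' Pearson correlation of each gene's normalized expression with a
#' per-cell covariate (e.g. tail-current maximal amplitude), typically
#' restricted to the differentially expressed genes.  Zero-variance genes
#' return `NA` with a flag.
#'
#' @param norm A [size_factor_normalize()] result or matrix.
#' @param covariate Numeric covariate, one value per cell, or the name of
#'   a covariate column carried by `norm`.
#' @param genes Optional subset of gene names.
#' @return Data frame: `gene`, `pearson_r`, `zero_variance`.
#' @export
correlate_with_feature <- function(norm, covariate, genes = NULL) {
  mat <- if (inherits(norm, "normalized_counts")) norm$normalized else as.matrix(norm)
  if (is.character(covariate) && length(covariate) == 1) {
    if (!inherits(norm, "normalized_counts") || is.null(norm$covariates) ||
        !covariate %in% names(norm$covariates))
      stop("correlate_with_feature: covariate column '", covariate, "' not found")
    covariate <- norm$covariates[[covariate]]
  }
  if (length(covariate) != ncol(mat))
    stop("correlate_with_feature: covariate missing for cells: ",
         paste(colnames(mat)[seq_len(min(3, ncol(mat)))], collapse = ", "),
         if (ncol(mat) > 3) ", ..." else "")
  if (anyNA(covariate))
    stop("correlate_with_feature: covariate missing for cells: ",
         paste(colnames(mat)[is.na(covariate)], collapse = ", "))
  if (ncol(mat) < 3)
    stop("correlate_with_feature: need >= 3 cells")
  if (!is.null(genes)) mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1, sd)
  r <- rep(NA_real_, nrow(mat))
  ok <- sds > 0 & sd(covariate) > 0
  r[ok] <- apply(mat[ok, , drop = FALSE], 1, cor, y = covariate)
  data.frame(gene = rownames(mat), pearson_r = r, zero_variance = !ok,
             stringsAsFactors = FALSE, row.names = NULL)
}
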