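test_that("marker QC keeps exactly the hand-enumerated survivors", {
  m <- toy_qc_matrix()
  out <- qc_filter_cells(m)
  expect_equal(ncol(out$counts), 3)          # drops the Th- and Pvalb+ cells
  expect_identical(colnames(out$counts), c("c1", "c2", "c5"))
  att <- attr(out, "attrition")
  expect_equal(att$cells[att$criterion == "retained"], 3)

  clean <- m$counts[, c(1, 2, 5)]
  m2 <- count_matrix(clean, m$group[c(1, 2, 5)])
  expect_identical(qc_filter_cells(m2)$counts, clean)   # identity when all pass

  m3 <- count_matrix(m$counts[-1, , drop = FALSE], m$group)
  expect_error(qc_filter_cells(m3), "Th")

  # the default marker sets are the published seven genes
  expect_identical(eval(formals(qc_filter_cells)$positive_markers),
                   c("Th", "Slc6a3", "Slc18a2"))
  expect_identical(eval(formals(qc_filter_cells)$negative_markers),
                   c("Pvalb", "Tmem119", "P2ry12", "Aldh1l1"))
})

test_that("the expression filter applies the >=1-count-in->=80%-of-one-group rule", {
  counts <- rbind(
    in_grp1   = c(2, 2, 2, 2, 0,  0, 0, 0, 0, 0),   # 0.8 of group 1
    allzero   = rep(0, 10),
    everywhere = rep(3, 10),
    weak      = c(1, 0, 0, 0, 0,  0, 0, 1, 0, 0))
  colnames(counts) <- paste0("c", 1:10)
  cm <- count_matrix(counts, rep(c("A", "B"), each = 5))
  kept <- filter_expressed(cm)
  expect_identical(rownames(kept$counts), c("in_grp1", "everywhere"))
})

test_that("median-of-ratios size factors match hand evaluations and invariances", {
  cts <- matrix(c(4, 10, 7, 4, 10, 7), nrow = 3,
                dimnames = list(paste0("g", 1:3), c("a", "b")))
  sf <- size_factor_normalize(count_matrix(cts, c("A", "B")))$size_factors
  expect_equal(unname(sf), c(1, 1))

  cts2 <- cbind(a = c(4, 10, 7), b = c(8, 20, 14))
  rownames(cts2) <- paste0("g", 1:3)
  sf2 <- size_factor_normalize(count_matrix(cts2, c("A", "B")))$size_factors
  expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2)))

  n10 <- size_factor_normalize(count_matrix(cts2 * 10, c("A", "B")))
  n1 <- size_factor_normalize(count_matrix(cts2, c("A", "B")))
  expect_equal(n10$size_factors, n1$size_factors)
  expect_equal(n10$normalized, n1$normalized * 10)
})

test_that("size factors commute with cell permutation and cross-check DESeq2", {
  out <- synth_patchseq(n_genes = 150, n_cells_per_group = c(10, 10),
                        contam_fraction = 0, seed = 11)
  cm <- out$matrix
  sf <- size_factor_normalize(cm)$size_factors
  perm <- sample(ncol(cm$counts))
  cmp <- count_matrix(cm$counts[, perm], cm$group[perm])
  expect_equal(unname(size_factor_normalize(cmp)$size_factors),
               unname(sf[perm]))
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 scaling
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 6)), rep(1, 6))
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(3:200, 1))
    if (i %% 5 == 0) p[sample(length(p), 2)] <- NA
    if (i %% 7 == 0) p[2:3] <- p[1]          # ties share adjusted values
    expect_identical(bh_adjust(p), brute_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential expression recovers planted effects and is order-invariant", {
  out <- synth_patchseq(n_genes = 800, n_cells_per_group = c(30, 30),
                        deg_fraction = 30 / 800, fold_change = 2,
                        corr_genes = 0, contam_fraction = 0, seed = 21)
  cm <- filter_expressed(qc_filter_cells(out$matrix))
  de <- differential_expression(size_factor_normalize(cm))
  hits <- de$gene[de$deg]
  planted <- out$ground_truth$deg$gene
  expect_gte(sum(planted %in% hits), 0.85 * length(planted))
  fdr_emp <- mean(!(hits %in% planted))
  expect_lte(fdr_emp, 0.2)
  # flag is exactly the strict double cutoff
  expect_identical(de$deg, de$fdr < 0.1 & de$abs_fc > 1.25)
  s <- attr(de, "summary")
  expect_equal(s$n_deg, s$n_up + s$n_down)

  norm <- size_factor_normalize(cm)
  gperm <- sample(nrow(norm$normalized))
  cperm <- sample(ncol(norm$normalized))
  de2 <- differential_expression(norm$normalized[gperm, cperm],
                                 group = norm$group[cperm])
  de2 <- de2[match(de$gene, de2$gene), ]
  expect_equal(de2$p, de$p, tolerance = 1e-12)
  expect_equal(de2$fold_change, de$fold_change, tolerance = 1e-12)
})

test_that("label permutation gives an essentially empty DEG list", {
  out <- synth_patchseq(n_genes = 600, n_cells_per_group = c(30, 30),
                        deg_fraction = 0.05, fold_change = 2,
                        corr_genes = 0, contam_fraction = 0, seed = 31)
  norm <- size_factor_normalize(filter_expressed(out$matrix))
  set.seed(32)
  de <- differential_expression(norm$normalized,
                                group = sample(norm$group))
  expect_lte(sum(de$deg), 2)
})

test_that("zero-variance genes get p = 1 and a flag", {
  mat <- rbind(flat = rep(5, 12), var = c(rnorm(6, 10), rnorm(6, 30)))
  colnames(mat) <- paste0("c", 1:12)
  de <- differential_expression(mat, group = rep(c("A", "B"), each = 6))
  expect_true(de$zero_variance[de$gene == "flat"])
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_false(de$deg[de$gene == "flat"])
})

test_that("raw p-values are calibrated under the global null", {
  fr <- vapply(1:50, function(s) {
    out <- synth_patchseq(n_genes = 400, n_cells_per_group = c(30, 30),
                          deg_fraction = 0, corr_genes = 0,
                          contam_fraction = 0, seed = 100 + s)
    norm <- size_factor_normalize(filter_expressed(out$matrix))
    de <- differential_expression(norm)
    mean(de$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.01)
})

test_that("physiology correlation is exact on constructed cases", {
  covar <- c(1, 3, 5, 7, 11, 13)
  mat <- rbind(lin = 2 * covar + 5, flat = rep(4, 6),
               anti = -covar)
  colnames(mat) <- paste0("c", 1:6)
  r <- correlate_with_feature(mat, covar)
  expect_equal(r$pearson_r[r$gene == "lin"], 1)
  expect_equal(r$pearson_r[r$gene == "anti"], -1)
  expect_true(is.na(r$pearson_r[r$gene == "flat"]))
  expect_true(r$zero_variance[r$gene == "flat"])
  expect_error(correlate_with_feature(mat, c(1, 2, NA, 4, 5, 6)),
               "missing for cells: c3")
  expect_error(correlate_with_feature(mat, 1:3), "missing")
})

test_that("counts round-trip through MTX and dense TSV directories", {
  out <- synth_patchseq(n_genes = 60, n_cells_per_group = c(5, 5), seed = 41)
  for (fmt in c("mtx", "tsv")) {
    d <- file.path(tempdir(), paste0("counts_", fmt))
    write_counts(out$matrix, d, format = fmt)
    back <- read_counts(d)
    expect_equal(back$counts, out$matrix$counts)
    expect_equal(as.character(back$group), as.character(out$matrix$group))
    expect_equal(back$covariates$tail_pA, out$matrix$covariates$tail_pA,
                 tolerance = 1e-9)
  }
})
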