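#' Read and write count matrices
#'
#' Counts travel either as MatrixMarket MTX with `genes.tsv` and
#' `cells.tsv` sidecars (the cells file carries `cell`, `group` and any
#' covariate columns), or as a single dense TSV whose first column is the
#' gene symbol, with a matching `cells.tsv`.
#'
#' @param path Directory holding `matrix.mtx` (or `counts.tsv`),
#'   `genes.tsv` and `cells.tsv`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  cells <- read.delim(file.path(path, "cells.tsv"), stringsAsFactors = FALSE)
  if (!all(c("cell", "group") %in% names(cells)))
    stop("read_counts: cells.tsv needs 'cell' and 'group' columns")
  mtx <- file.path(path, "matrix.mtx")
  if (file.exists(mtx)) {
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- read.delim(file.path(path, "genes.tsv"),
                        stringsAsFactors = FALSE)[[1]]
    dimnames(m) <- list(genes, cells$cell)
  } else {
    tab <- read.delim(file.path(path, "counts.tsv"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  }
  cov_cols <- setdiff(names(cells), c("cell", "group"))
  count_matrix(m, cells$group,
               covariates = if (length(cov_cols))
                 cells[, cov_cols, drop = FALSE] else NULL)
}

#' @rdname read_counts
#' @param x A [count_matrix()].
#' @param format `"mtx"` or `"tsv"`.
#' @export
write_counts <- function(x, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cells <- data.frame(cell = colnames(x$counts), group = x$group,
                      stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) cells <- cbind(cells, x$covariates)
  write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    write.table(data.frame(gene = rownames(x$counts)),
                file.path(path, "genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    tab <- data.frame(gene = rownames(x$counts), x$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, file.path(path, "counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
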