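#' Per-cell mean intensities under a label mask
#'
#' Given an integer label mask (0 = background) and an intensity image of
#' the same shape, returns pixel count, mean and median intensity for
#' every labelled cell.  Labels may be any positive integers; background
#' pixels are never counted.
#'
#' @param mask Integer matrix; 0 is background, `k > 0` is cell `k`.
#' @param image Numeric matrix of intensities, same dimensions.
#' @return Data frame: `label`, `n_pixels`, `mean_intensity`,
#'   `median_intensity`.  Empty (with a warning) if the mask has no
#'   labels.
#' @export
cell_mask_intensities <- function(mask, image) {
  mask <- as.matrix(mask); image <- as.matrix(image)
  if (!all(dim(mask) == dim(image)))
    stop("cell_mask_intensities: mask and image dimensions differ ",
         "(resize the mask first, see resize_mask_nearest)")
  sel <- mask > 0
  if (!any(sel)) {
    warning("cell_mask_intensities: empty mask")
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      mean_intensity = numeric(0),
                      median_intensity = numeric(0)))
  }
  f <- factor(mask[sel])
  vals <- image[sel]
  data.frame(label = as.integer(levels(f)),
             n_pixels = as.integer(table(f)),
             mean_intensity = as.numeric(tapply(vals, f, mean)),
             median_intensity = as.numeric(tapply(vals, f, median)),
             row.names = NULL)
}

#' Nearest-neighbour mask resize
#'
#' Resizes a label mask to new dimensions by nearest-neighbour index
#' mapping (pixel centres), so labels are never interpolated.  Used when
#' masks were produced at a different scale than the intensity image.
#'
#' @param mask Integer matrix.
#' @param dim_out Length-2 integer vector `c(rows, cols)`.
#' @return The resized mask.
#' @export
resize_mask_nearest <- function(mask, dim_out) {
  mask <- as.matrix(mask)
  ri <- pmin(nrow(mask), floor((seq_len(dim_out[1]) - 0.5) *
                                 nrow(mask) / dim_out[1]) + 1L)
  ci <- pmin(ncol(mask), floor((seq_len(dim_out[2]) - 0.5) *
                                 ncol(mask) / dim_out[2]) + 1L)
  mask[ri, ci, drop = FALSE]
}

#' Select the brightest slice of an image stack
#'
#' Returns the index of the stack slice with the highest mean intensity
#' (the per-slice mean is the brightness metric).
#'
#' @param stack 3-d numeric array (rows x cols x slices).
#' @return Integer slice index.
#' @export
brightest_slice <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  which.max(apply(stack, 3, mean))
}

#' Read a 16-bit TIFF as an integer matrix
#'
#' Thin wrapper over [tiff::readTIFF()] returning raw integer values
#' (suitable both for label masks and for intensity images).
#'
#' @param path TIFF file path.
#' @return Integer matrix (or array for multi-channel images).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(img) <- "integer"
  img
}

#' Compare two per-cell intensity distributions
#'
#' Two-sample Kolmogorov-Smirnov test (D statistic and asymptotic
#' two-sided p) between pooled per-cell mean intensities of two groups,
#' plus the empirical cumulative distribution curves for plotting.
#'
#' @param sample_a,sample_b Numeric vectors (>= 2 values each).
#' @return A list of class `ks_result`: `D`, `p`, `n_a`, `n_b`, `ecdf_a`,
#'   `ecdf_b` (data frames `value`, `cum_prob`).
#' @export
compare_cumulative <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("compare_cumulative: each sample needs >= 2 values")
  ks <- suppressWarnings(ks.test(sample_a, sample_b))
  curve <- function(v) {
    s <- sort(unique(v))
    data.frame(value = s, cum_prob = ecdf(v)(s))
  }
  structure(list(D = unname(ks$statistic), p = ks$p.value,
                 n_a = length(sample_a), n_b = length(sample_b),
                 ecdf_a = curve(sample_a), ecdf_b = curve(sample_b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.3g (n = %d vs %d)\n",
              x$D, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Synthesize a labelled-mask / intensity-image pair
#'
#' Places non-overlapping rectangular "cells" on a background and draws
#' pixel intensities around planted per-cell means, returning the mask,
#' the image and the planted means.  Used to exercise the imaging stage
#' end to end without microscope data.
#'
#' @param n_cells Number of cells.
#' @param dim_px Image size `c(rows, cols)`.
#' @param mean_range Range the planted per-cell means are drawn from.
#' @param noise_sd Pixel noise around each cell's mean.
#' @param background Background intensity.
#' @param seed Integer seed.
#' @return List: `mask`, `image`, `ground_truth` (`label`, `mean`).
#' @export
synth_mask_image <- function(n_cells = 20, dim_px = c(128, 128),
                             mean_range = c(500, 3000), noise_sd = 0,
                             background = 100, seed = 1L) {
  set.seed(seed)
  mask <- matrix(0L, dim_px[1], dim_px[2])
  img <- matrix(background, dim_px[1], dim_px[2])
  side <- max(3L, floor(min(dim_px) / ceiling(sqrt(n_cells)) / 2))
  grid_n <- floor(dim_px / (2 * side))
  slots <- expand.grid(r = seq_len(grid_n[1]), c = seq_len(grid_n[2]))
  if (nrow(slots) < n_cells)
    stop("synth_mask_image: too many cells for the image size")
  slots <- slots[sample(nrow(slots), n_cells), ]
  means <- runif(n_cells, mean_range[1], mean_range[2])
  for (k in seq_len(n_cells)) {
    r0 <- (slots$r[k] - 1) * 2 * side + 2
    c0 <- (slots$c[k] - 1) * 2 * side + 2
    rows <- r0:(r0 + side - 1); cols <- c0:(c0 + side - 1)
    mask[rows, cols] <- k
    px <- length(rows) * length(cols)
    vals <- means[k] + if (noise_sd > 0) rnorm(px, 0, noise_sd) else 0
    # keep the realized per-cell mean exactly on target
    img[rows, cols] <- vals - mean(vals) + means[k]
  }
  list(mask = mask, image = img,
       ground_truth = data.frame(label = seq_len(n_cells), mean = means))
}
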