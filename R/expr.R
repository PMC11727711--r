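#' Counts per million
#'
#' `count * 1e6 / library size`, with library size the column (sample) total.
#'
#' @param counts Genes x samples matrix of non-negative raw counts.
#' @return Matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Group log2 fold change on a CPM matrix
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` per gene, with the
#' group means taken across samples. The pseudocount keeps zero-expression
#' genes finite; swapping the groups negates the value.
#'
#' @param x Genes x samples expression matrix (typically [cpm()] output).
#' @param group_a,group_b Column indices or names of the two groups
#'   (non-empty).
#' @param pseudocount Added to both means (default 1).
#' @return Named numeric vector, one value per gene.
#' @export
group_log2fc <- function(x, group_a, group_b, pseudocount = 1) {
  a <- x[, group_a, drop = FALSE]
  b <- x[, group_b, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stop("both groups must be non-empty")
  log2((rowMeans(a) + pseudocount) / (rowMeans(b) + pseudocount))
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' `dCt = Ct(target) - Ct(reference)` within each condition;
#' `ddCt = dCt(sample) - dCt(calibrator)`; relative expression is
#' `2^-ddCt`. Technical-replicate Ct values (vectors) are averaged before
#' the differences are taken.
#'
#' @param ct_target,ct_reference Sample-condition Ct values for the target
#'   and the reference gene (e.g. beta-actin); replicate vectors allowed.
#' @param ct_target_cal,ct_reference_cal The calibrator condition's Ct
#'   values.
#' @return Relative expression (1 when ddCt = 0, 0.5 per extra target
#'   cycle).
#' @export
ddct_fold <- function(ct_target, ct_reference, ct_target_cal,
                      ct_reference_cal) {
  cts <- c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be finite and positive")
  }
  dct_sample <- mean(ct_target) - mean(ct_reference)
  dct_cal <- mean(ct_target_cal) - mean(ct_reference_cal)
  2^-(dct_sample - dct_cal)
}
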