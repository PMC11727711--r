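#' Normalize windowed read depth against a reference population
#'
#' Each sample's window counts are first divided by its library-size factor
#' (total count over all windows, rescaled so the factors average 1), which
#' removes genome-wide coverage differences; each window is then divided by
#' the reference-group median for that window, so a diploid window in a
#' reference-like sample has ratio 1. Windows whose reference median is zero
#' are masked (`NA`).
#'
#' @param depth A `depth_matrix` (see [simulate_depth()] / [read_depth()]).
#' @param reference_samples Column indices or names of the reference group
#'   (e.g. the Pekin-like samples).
#' @return List with `windows`, `ratio` and `log2_fc` matrices (windows x
#'   samples).
#' @export
normalize_depth <- function(depth, reference_samples) {
  stopifnot(inherits(depth, "depth_matrix"))
  counts <- depth$counts
  if (length(reference_samples) == 0) stop("reference group is empty")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total depth")
  factor <- lib / mean(lib)
  scaled <- sweep(counts, 2, factor, "/")
  ref_med <- apply(scaled[, reference_samples, drop = FALSE], 1, stats::median)
  ratio <- sweep(scaled, 1, ref_med, "/")
  ratio[ref_med == 0, ] <- NA_real_
  list(windows = depth$windows, ratio = ratio, log2_fc = log2(ratio))
}

#' Classify a depth ratio into a copy-number class
#'
#' Maps the depth ratio (relative to the diploid reference) to the nearest of
#' the classes 0, 0.5, 1, 1.5, 2 — homozygous loss, loss of heterozygosity,
#' normal diploidy, heterozygous duplication, homozygous duplication — with
#' class boundaries at the midpoints (0.25, 0.75, 1.25, 1.75) and ties
#' rounding up. Ratios above 2.25 are called `"COMPLEX"` (complex
#' duplication).
#'
#' @param ratio Numeric vector of depth ratios (>= 0; `NA` passes through).
#' @return Character vector over `{"0", "0.5", "1", "1.5", "2", "COMPLEX"}`.
#' @export
classify_cn <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stop("depth ratios must be non-negative")
  classes <- c("0", "0.5", "1", "1.5", "2")
  # right-open intervals so boundary values round up to the higher class
  idx <- findInterval(ratio, c(0.25, 0.75, 1.25, 1.75, 2.25),
                      left.open = FALSE) + 1L
  out <- rep(NA_character_, length(ratio))
  ok <- !is.na(ratio)
  out[ok & idx <= 5] <- classes[idx[ok & idx <= 5]]
  out[ok & idx == 6L] <- "COMPLEX"
  out
}

#' Call copy-number classes for every window and sample
#'
#' @param depth A `depth_matrix`.
#' @param reference_samples Reference group for [normalize_depth()].
#' @return Long-format data frame: `chrom`, `start`, `end`, `sample`,
#'   `depth_ratio`, `log2_fc`, `cn_class`.
#' @export
call_cnv <- function(depth, reference_samples) {
  nd <- normalize_depth(depth, reference_samples)
  n_w <- nrow(nd$windows)
  samples <- colnames(nd$ratio)
  out <- data.frame(
    chrom = rep(nd$windows$chrom, times = length(samples)),
    start = rep(nd$windows$start, times = length(samples)),
    end = rep(nd$windows$end, times = length(samples)),
    sample = rep(samples, each = n_w),
    depth_ratio = as.vector(nd$ratio),
    log2_fc = as.vector(nd$log2_fc),
    stringsAsFactors = FALSE
  )
  out$cn_class <- classify_cn(out$depth_ratio)
  out
}
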