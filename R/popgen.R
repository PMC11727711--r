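#' Per-variant alternate-allele frequency in one population
#'
#' @param geno Samples x variants dosage matrix.
#' @param samples Row indices or rownames of the population's samples.
#' @return List with `p` (alt-allele frequency over non-missing alleles, `NA`
#'   when every genotype is missing) and `n` (non-missing allele count), each
#'   one value per variant.
#' @export
allele_freq <- function(geno, samples) {
  g <- geno[samples, , drop = FALSE]
  if (nrow(g) == 0L) stop("population is empty")
  n <- 2L * colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  p <- ifelse(n > 0, ac / n, NA_real_)
  list(p = p, n = n)
}

#' Absolute allele-frequency difference between two populations
#'
#' @param p1,p2 Allele frequencies (vectors recycle).
#' @return `|p1 - p2|`.
#' @export
delta_af <- function(p1, p2) abs(p1 - p2)

#' Hudson's two-population FST estimator for one or more SNPs
#'
#' Numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, where `n1`, `n2` count sampled alleles. Undefined
#' (`NA`) when the denominator is zero, i.e. both populations fixed for the
#' same allele. Negative estimates are reported as computed.
#'
#' @param p1,p2 Alt-allele frequencies per population.
#' @param n1,n2 Non-missing allele counts per population (each must be >= 2).
#' @return List with `fst`, `num`, `den` (the window averager needs the
#'   components).
#' @references Hudson, Slatkin & Maddison (1992); ratio-of-averages windowing
#'   after Bhatia et al. (2013).
#' @export
fst_hudson <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1, na.rm = TRUE) || any(n2 <= 1, na.rm = TRUE)) {
    stop("Hudson FST needs at least 2 sampled alleles per population")
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  list(fst = fst, num = num, den = den)
}

#' Weir-Cockerham two-population per-SNP FST (alternative estimator)
#'
#' The 1984 variance-components estimator (`theta = a / (a + b + c)`) for two
#' populations with possibly unequal sample sizes, computed from allele
#' frequencies alone (no inbreeding/heterozygosity correction term, i.e. the
#' haploid-sampling form commonly used on frequency tables).
#'
#' @inheritParams fst_hudson
#' @return List with `fst`, `num` (a) and `den` (a + b + c).
#' @export
fst_weir_cockerham <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1, na.rm = TRUE) || any(n2 <= 1, na.rm = TRUE)) {
    stop("Weir-Cockerham FST needs at least 2 sampled alleles per population")
  }
  r <- 2
  n_bar <- (n1 + n2) / r
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2)
  den <- a + b
  fst <- ifelse(!is.na(den) & den > 0, a / den, NA_real_)
  list(fst = fst, num = a, den = den)
}

#' Divergence table for one two-population contrast
#'
#' Computes per-variant allele frequencies, allele counts, delta-AF and FST
#' for a pair of populations. Variants where either population has no
#' non-missing allele are dropped.
#'
#' @param geno Samples x variants dosage matrix.
#' @param variants Variant table aligned with `geno` columns.
#' @param pop1,pop2 Sample indices or rownames of the two populations.
#' @param estimator `"hudson"` (default) or `"wc"` (Weir-Cockerham).
#' @return Data frame with `chrom`, `pos`, `p1`, `p2`, `n1`, `n2`,
#'   `delta_af`, `fst`, plus the `num`/`den` components used by
#'   [window_fst()].
#' @export
divergence_table <- function(geno, variants, pop1, pop2,
                             estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(nrow(variants) == ncol(geno))
  a1 <- allele_freq(geno, pop1)
  a2 <- allele_freq(geno, pop2)
  ok <- a1$n >= 2 & a2$n >= 2
  f <- switch(estimator,
    hudson = fst_hudson(a1$p[ok], a1$n[ok], a2$p[ok], a2$n[ok]),
    wc = fst_weir_cockerham(a1$p[ok], a1$n[ok], a2$p[ok], a2$n[ok])
  )
  out <- data.frame(
    chrom = variants$chrom[ok], pos = variants$pos[ok],
    p1 = a1$p[ok], p2 = a2$p[ok], n1 = a1$n[ok], n2 = a2$n[ok],
    delta_af = delta_af(a1$p[ok], a2$p[ok]),
    fst = f$fst, num = f$num, den = f$den,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Windowed FST averages (ratio of averages)
#'
#' Tiles each chromosome with fixed-width, half-open windows anchored at
#' coordinate 1 (`[1, w+1)`, `[w+1, 2w+1)`, ...) and reports per-window FST as
#' the ratio of the summed estimator numerators to the summed denominators —
#' the recommended way to average FST, more stable than a mean of ratios.
#' Windows containing no usable SNP are omitted.
#'
#' @param divergence A [divergence_table()].
#' @param window_bp Window width in bp (default 10 kb).
#' @return Data frame: `chrom`, `start`, `end` (half-open), `mean_fst`,
#'   `n_snps`.
#' @export
window_fst <- function(divergence, window_bp = 10000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  d <- divergence[!is.na(divergence$den) & divergence$den > 0, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_fst = numeric(), n_snps = integer()))
  }
  start <- as.integer(floor((d$pos - 1) / window_bp) * window_bp + 1)
  key <- paste(d$chrom, start, sep = "\r")
  num <- tapply(d$num, key, sum)
  den <- tapply(d$den, key, sum)
  cnt <- tapply(d$num, key, length)
  parts <- do.call(rbind, strsplit(names(num), "\r", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1], start = as.integer(parts[, 2]),
    end = as.integer(parts[, 2]) + as.integer(window_bp),
    mean_fst = as.numeric(num / den), n_snps = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
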