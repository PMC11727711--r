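#' Ancestry-informative SNPs of a candidate region
#'
#' Variants inside the region whose founder-contrast allele-frequency
#' difference exceeds the threshold (the delta-AF > 0.8 screen used to pick
#' markers whose alleles identify founder ancestry).
#'
#' @param divergence Founder-contrast [divergence_table()] (population 1 =
#'   first founder breed).
#' @param region `list(chrom =, start =, end =)`, 1-based inclusive.
#' @param threshold Delta-AF cutoff, strict (default 0.8).
#' @return The qualifying rows of `divergence`, sorted by position, with an
#'   `p1_major` logical column (is the alt allele the majority allele of
#'   population 1). Warns when empty.
#' @export
informative_snps <- function(divergence, region, threshold = 0.8) {
  stopifnot(region$start <= region$end)
  sel <- divergence$chrom == region$chrom &
    divergence$pos >= region$start & divergence$pos <= region$end &
    !is.na(divergence$delta_af) & divergence$delta_af > threshold
  out <- divergence[sel, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no informative SNPs in the candidate region at delta-AF > ",
            threshold)
  }
  out$p1_major <- out$p1 > out$p2
  rownames(out) <- NULL
  out
}

ANCESTRY_STATES <- c("HOM_P1", "HET", "HOM_P2", "UNKNOWN")

#' Founder-ancestry painting of individuals across informative SNPs
#'
#' At each informative SNP, the diplotype state is the number of copies of
#' the population-1-major allele: 2 copies gives `HOM_P1`, 1 `HET`, 0
#' `HOM_P2`; missing genotypes are `UNKNOWN`. Optional majority-vote
#' smoothing over a centred 3-SNP window absorbs isolated genotyping errors
#' (off by default; noise-free simulated data needs none).
#'
#' @param geno Samples x variants dosage matrix (full matrix; informative
#'   SNPs are picked out by position).
#' @param variants Variant table aligned with `geno`.
#' @param info [informative_snps()] output.
#' @param smooth Apply 3-SNP majority smoothing (default `FALSE`).
#' @return Object of class `ancestry_path`: list with `pos` (informative SNP
#'   positions), `chrom`, and `states` (samples x SNPs character matrix of
#'   ancestry states).
#' @export
infer_ancestry <- function(geno, variants, info, smooth = FALSE) {
  if (nrow(info) == 0L) stop("no informative SNPs to paint ancestry with")
  key_all <- paste(variants$chrom, variants$pos)
  idx <- match(paste(info$chrom, info$pos), key_all)
  if (anyNA(idx)) stop("informative SNPs missing from the variant table")
  g <- geno[, idx, drop = FALSE]
  # dosage of the population-1-major allele
  d <- sweep(g, 2, ifelse(info$p1_major, 0, 2), function(gg, o) abs(o - gg))
  states <- matrix(ANCESTRY_STATES[4], nrow(g), ncol(g),
                   dimnames = list(rownames(geno), paste0(info$chrom, ":", info$pos)))
  states[!is.na(d) & d == 2] <- "HOM_P1"
  states[!is.na(d) & d == 1] <- "HET"
  states[!is.na(d) & d == 0] <- "HOM_P2"
  if (smooth && ncol(states) >= 3) {
    sm <- states
    for (j in 2:(ncol(states) - 1L)) {
      win <- states[, (j - 1L):(j + 1L), drop = FALSE]
      sm[, j] <- apply(win, 1, function(s) {
        s <- s[s != "UNKNOWN"]
        if (length(s) == 0) return("UNKNOWN")
        tab <- table(s)
        if (max(tab) >= 2) names(tab)[which.max(tab)] else s[2 %% length(s) + 1]
      })
    }
    states <- sm
  }
  structure(list(chrom = info$chrom[1], pos = info$pos, states = states),
            class = "ancestry_path")
}

#' Recombination breakpoints of each individual's ancestry path
#'
#' Scans each individual's ancestry states along the informative SNPs;
#' `UNKNOWN` states are skipped with the last known state carried over. Every
#' change between consecutive known states yields one breakpoint, reported as
#' the open interval between the two flanking informative SNPs — genotype
#' data cannot localize a crossover more finely than that.
#'
#' @param path An [infer_ancestry()] result.
#' @return Data frame: `sample_id`, `left`, `right` (flanking informative-SNP
#'   positions), `from`, `to` (states). Zero rows when no individual
#'   recombines.
#' @export
find_breakpoints <- function(path) {
  stopifnot(inherits(path, "ancestry_path"))
  res <- list()
  for (i in seq_len(nrow(path$states))) {
    s <- path$states[i, ]
    known <- which(s != "UNKNOWN")
    if (length(known) < 2) next
    sk <- s[known]
    chg <- which(sk[-1] != sk[-length(sk)])
    for (k in chg) {
      res[[length(res) + 1L]] <- data.frame(
        sample_id = rownames(path$states)[i],
        left = path$pos[known[k]], right = path$pos[known[k + 1L]],
        from = sk[k], to = sk[k + 1L], stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) {
    return(data.frame(sample_id = character(), left = numeric(),
                      right = numeric(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partition a candidate region into haplotype blocks
#'
#' Cuts the region at the union of all individuals' breakpoint intervals:
#' each gap between adjacent informative SNPs that is covered by at least one
#' breakpoint interval becomes a cut, and `k` distinct cut gaps yield `k + 1`
#' blocks. The per-individual block state is the consensus of its member-SNP
#' states, requiring at least `consensus` agreement among known states
#' (otherwise `UNKNOWN`).
#'
#' @param path An [infer_ancestry()] result.
#' @param breakpoints A [find_breakpoints()] table for the same path.
#' @param consensus Minimum member-SNP agreement fraction (default 0.8).
#' @return Object of class `haplotype_blocks`: data.frame `blocks` (`block`,
#'   `chrom`, `start`, `end`, `n_snps`) and matrix `states` (samples x
#'   blocks).
#' @export
partition_blocks <- function(path, breakpoints, consensus = 0.8) {
  stopifnot(inherits(path, "ancestry_path"))
  pos <- path$pos
  n_gap <- length(pos) - 1L
  cut <- rep(FALSE, max(n_gap, 0L))
  if (nrow(breakpoints) > 0) {
    for (k in seq_len(n_gap)) {
      cut[k] <- any(breakpoints$left <= pos[k] & breakpoints$right >= pos[k + 1L])
    }
  }
  block_id <- cumsum(c(1L, as.integer(cut)))
  n_blk <- max(block_id)
  blocks <- data.frame(
    block = seq_len(n_blk),
    chrom = path$chrom,
    start = vapply(seq_len(n_blk), function(b) min(pos[block_id == b]), numeric(1)),
    end = vapply(seq_len(n_blk), function(b) max(pos[block_id == b]), numeric(1)),
    n_snps = as.integer(table(block_id)),
    stringsAsFactors = FALSE
  )
  states <- matrix("UNKNOWN", nrow(path$states), n_blk,
                   dimnames = list(rownames(path$states),
                                   paste0("block", seq_len(n_blk))))
  for (b in seq_len(n_blk)) {
    mem <- path$states[, block_id == b, drop = FALSE]
    states[, b] <- apply(mem, 1, function(s) {
      s <- s[s != "UNKNOWN"]
      if (length(s) == 0) return("UNKNOWN")
      tab <- table(s)
      if (max(tab) / length(s) >= consensus) names(tab)[which.max(tab)]
      else "UNKNOWN"
    })
  }
  structure(list(blocks = blocks, states = states, block_id = block_id),
            class = "haplotype_blocks")
}

#' Block-phenotype concordance scores
#'
#' For black-beaked individuals (phenotype BF, GF or WB — the classes where
#' the feather locus is visible), the feather phenotype implies an ancestry
#' state at the true feather locus under the cross orientation (the `R`
#' allele is fixed in founder population 2): BF implies `HOM_P2`, GF `HET`,
#' WB `HOM_P1`. Each block is scored by the fraction of black-beaked
#' individuals whose block state matches the implied state; blocks scoring 1
#' are flagged as the candidate feather-locus interval.
#'
#' @param blocks A [partition_blocks()] result.
#' @param phenotype Character vector of phenotype classes, aligned with the
#'   rows of `blocks$states`.
#' @return Data frame: the block table plus `concordance` and `candidate`
#'   columns.
#' @export
block_concordance <- function(blocks, phenotype) {
  stopifnot(inherits(blocks, "haplotype_blocks"),
            length(phenotype) == nrow(blocks$states))
  implied <- c(BF = "HOM_P2", GF = "HET", WB = "HOM_P1")[phenotype]
  keep <- !is.na(implied)
  if (!any(keep)) stop("no black-beaked individuals to score concordance on")
  sc <- vapply(seq_len(nrow(blocks$blocks)), function(b) {
    mean(blocks$states[keep, b] == implied[keep])
  }, numeric(1))
  out <- blocks$blocks
  out$concordance <- sc
  out$candidate <- sc == 1
  out
}

#' Composite linkage-disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of genotype dosages over samples where both
#' are observed (composite LD; no phasing needed). Undefined (`NA`) when
#' either variant is monomorphic among the complete pairs.
#'
#' @param g1,g2 Dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2 || stats::var(g1) == 0 || stats::var(g2) == 0) {
    return(NA_real_)
  }
  stats::cor(g1, g2)^2
}

#' Three-step cross-breed causative-mutation screen
#'
#' Starting from the variants of a candidate region:
#' indels are excluded up front (reported separately); step 1 keeps variants
#' with founder-contrast FST at or above `fst_min`; step 2 keeps variants in
#' the intersection of the top-`decile` FST sets of every population-1
#' vs black-breed contrast (the "highest shared FST" rule); step 3 keeps
#' variants whose genotypes are completely concordant with phenotype in the
#' validation populations — the observed genotype-to-phenotype relation must
#' be one-to-one with zero exceptions. Survivors are nested
#' (step3 within step2 within step1). Final candidates in complete LD
#' (r-squared 1) are reported as one LD group.
#'
#' @param variants Variant table of the region (rows aligned with `geno`
#'   columns).
#' @param geno Samples x region-variants dosage matrix.
#' @param founder_div Founder-contrast [divergence_table()] restricted to the
#'   region (population 1 vs population 2, e.g. LC vs PK).
#' @param black_divs Named list of [divergence_table()]s for every
#'   population-1 vs black-breed contrast (e.g. LC vs MD, LC vs PT, LC vs
#'   BF), region-restricted.
#' @param validation_samples Row indices or rownames of the validation-
#'   population individuals in `geno`.
#' @param validation_phenotype Phenotype class per validation individual.
#' @param fst_min Step-1 threshold, inclusive (default 0.8).
#' @param decile Step-2 per-contrast upper quantile (default 0.9 = top
#'   decile).
#' @return Object of class `screen_report`: logical step flags per variant,
#'   `excluded_indels`, `final` candidate indices, and `ld_groups`.
#' @export
causative_screen <- function(variants, geno, founder_div, black_divs,
                             validation_samples, validation_phenotype,
                             fst_min = 0.8, decile = 0.9) {
  stopifnot(nrow(variants) == ncol(geno), length(black_divs) >= 1)
  if (length(validation_samples) == 0) stop("validation populations are empty")
  m <- nrow(variants)
  key <- paste(variants$chrom, variants$pos)
  is_indel <- variants$vtype == "indel"

  fst_of <- function(div) {
    f <- div$fst[match(key, paste(div$chrom, div$pos))]
    f
  }
  f0 <- fst_of(founder_div)
  step1 <- !is_indel & !is.na(f0) & f0 >= fst_min

  step2 <- step1
  for (bd in black_divs) {
    f <- fst_of(bd)
    thr <- stats::quantile(f, decile, na.rm = TRUE, names = FALSE)
    step2 <- step2 & !is.na(f) & f >= thr
  }

  gval <- geno[validation_samples, , drop = FALSE]
  step3 <- step2
  for (j in which(step2)) {
    g <- gval[, j]
    ph <- validation_phenotype
    ok <- !is.na(g)
    if (!any(ok)) { step3[j] <- FALSE; next }
    tab <- unique(data.frame(g = g[ok], ph = ph[ok]))
    # one-to-one: no genotype with two phenotypes, no phenotype with two genotypes
    step3[j] <- !anyDuplicated(tab$g) && !anyDuplicated(tab$ph)
  }

  final <- which(step3)
  ld_groups <- list()
  if (length(final) > 0) {
    assigned <- rep(NA_integer_, length(final))
    gid <- 0L
    for (a in seq_along(final)) {
      if (!is.na(assigned[a])) next
      gid <- gid + 1L
      assigned[a] <- gid
      if (a < length(final)) {
        for (b in (a + 1L):length(final)) {
          if (is.na(assigned[b])) {
            r2 <- ld_r2(geno[, final[a]], geno[, final[b]])
            if (!is.na(r2) && r2 >= 1 - 1e-12) assigned[b] <- gid
          }
        }
      }
    }
    ld_groups <- split(final, assigned)
  }
  structure(
    list(variants = variants, step1 = step1, step2 = step2, step3 = step3,
         excluded_indels = which(is_indel), final = final,
         ld_groups = ld_groups),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Causative-mutation screen\n")
  cat(sprintf("  region variants : %d (%d indels excluded)\n",
              nrow(x$variants), length(x$excluded_indels)))
  cat(sprintf("  step 1 (founder FST)        : %d\n", sum(x$step1)))
  cat(sprintf("  step 2 (shared top FST)     : %d\n", sum(x$step2)))
  cat(sprintf("  step 3 (validation concord) : %d\n", sum(x$step3)))
  if (length(x$final)) {
    v <- x$variants[x$final, ]
    cat("  final candidates:",
        paste(paste0(v$chrom, ":", v$pos), collapse = ", "), "\n")
    cat(sprintf("  complete-LD groups: %d\n", length(x$ld_groups)))
  } else {
    cat("  no surviving candidates\n")
  }
  invisible(x)
}
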