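#' Two-locus epistasis segregation model for duck plumage colour
#'
#' Constructs the genotype-to-phenotype map for the two autosomal plumage loci
#' segregating in a Liancheng-type x Pekin-type duck cross. The `Bb` locus
#' controls melanin synthesis in the beak and feet (`B` dominant, enabling
#' synthesis); the `Rr` locus controls melanin deposition in the feather with
#' incomplete dominance (`RR` black, `Rr` grey, `rr` white feathers). `bb`
#' genotypes are epistatic over `Rr`: they give white feathers with a yellow
#' beak regardless of the `Rr` genotype.
#'
#' Phenotype classes:
#' \describe{
#'   \item{BF}{black-feathered, black beak (`B_RR`)}
#'   \item{GF}{grey-feathered, black beak (`B_Rr`)}
#'   \item{WB}{white-feathered, black beak (`B_rr`)}
#'   \item{WY}{white-feathered, yellow beak (`bb__`)}
#' }
#'
#' @param phenotype_map Function of `(b_count, r_count)` (counts of `B` and `R`
#'   alleles, each in 0:2) returning a single phenotype label. The default
#'   implements the epistasis/incomplete-dominance map above.
#' @param classes Character vector of phenotype classes, in reporting order.
#' @param locus_names Names of the two loci.
#' @return An object of class `segregation_model`.
#' @examples
#' m <- segregation_model()
#' phenotype_of(m, b_count = 0, r_count = 2)  # "WY": bb masks Rr
#' enumerate_f2_ratio(m)                      # 3:6:3:4 out of 16
#' @export
segregation_model <- function(phenotype_map = NULL,
                              classes = c("BF", "GF", "WB", "WY"),
                              locus_names = c("Bb", "Rr")) {
  if (is.null(phenotype_map)) {
    phenotype_map <- function(b_count, r_count) {
      if (b_count == 0) return("WY")
      switch(as.character(r_count), "2" = "BF", "1" = "GF", "0" = "WB")
    }
  }
  stopifnot(is.function(phenotype_map), length(classes) >= 1)
  obj <- structure(
    list(phenotype_map = phenotype_map, classes = classes,
         locus_names = locus_names),
    class = "segregation_model"
  )
  # the map must be total over the 9 diplotype combinations
  for (b in 0:2) for (r in 0:2) {
    ph <- phenotype_map(b, r)
    if (!(is.character(ph) && length(ph) == 1L && ph %in% classes)) {
      stop("phenotype_map must return a single class label for every ",
           "(b_count, r_count) pair; failed at (", b, ", ", r, ")")
    }
  }
  obj
}

#' Apply a segregation model's phenotype map
#'
#' @param model A [segregation_model()].
#' @param b_count,r_count Allele counts at the two loci, vectors over 0:2
#'   (recycled to common length).
#' @return Character vector of phenotype class labels.
#' @export
phenotype_of <- function(model, b_count, r_count) {
  stopifnot(inherits(model, "segregation_model"))
  n <- max(length(b_count), length(r_count))
  b <- rep_len(as.integer(b_count), n)
  r <- rep_len(as.integer(r_count), n)
  if (any(is.na(b) | is.na(r)) || any(b < 0 | b > 2 | r < 0 | r > 2)) {
    stop("allele counts must be in 0:2")
  }
  vapply(seq_len(n), function(i) model$phenotype_map(b[i], r[i]), character(1))
}

#' Exact F2 phenotype-class probabilities under a two-locus model
#'
#' Enumerates the 16 equiprobable gamete combinations of a dihybrid
#' `BbRr x BbRr` intercross (allele-count marginals 1/4, 1/2, 1/4 at each
#' locus, loci unlinked) and sums probabilities by phenotype class. The
#' default model yields the 3:6:3:4 ratio.
#'
#' @param model A [segregation_model()].
#' @return Named numeric vector of class probabilities (sums to 1), in the
#'   model's class order.
#' @export
enumerate_f2_ratio <- function(model) {
  stopifnot(inherits(model, "segregation_model"))
  marg <- c(1, 2, 1) / 4  # P(allele count = 0, 1, 2) in an F2
  p <- stats::setNames(numeric(length(model$classes)), model$classes)
  for (b in 0:2) for (r in 0:2) {
    ph <- model$phenotype_map(b, r)
    p[ph] <- p[ph] + marg[b + 1L] * marg[r + 1L]
  }
  p
}

#' Expected class counts for a given cohort size
#'
#' Real-valued expectations are `n * p_k`. The integer view rounds
#' half-away-from-zero, then repairs the class with the largest remainder so
#' the integers sum to `n` (at cohort size 1,281 under 3:6:3:4 this gives
#' 240, 481, 240, 320).
#'
#' @param n Total cohort size (non-negative).
#' @param ratio Named per-class probabilities summing to 1 (e.g. from
#'   [enumerate_f2_ratio()]), or unnormalized weights if `normalize = TRUE`.
#' @param normalize If `TRUE`, rescale `ratio` to sum to 1 first.
#' @return List with `expected` (real-valued) and `rounded` (integers summing
#'   to `n`), both named by class.
#' @export
expected_counts <- function(n, ratio, normalize = FALSE) {
  stopifnot(length(n) == 1L, n >= 0)
  if (normalize) ratio <- ratio / sum(ratio)
  if (abs(sum(ratio) - 1) > 1e-8) {
    stop("class probabilities must sum to 1 (use normalize = TRUE for weights)")
  }
  e <- n * ratio
  rounded <- trunc(e) + (e - trunc(e) >= 0.5)  # round half away from zero
  deficit <- round(n - sum(rounded))
  if (deficit != 0) {
    rem <- e - trunc(e)
    # push the discrepancy onto the class(es) with the largest remainder
    ord <- order(rem, decreasing = deficit > 0)
    for (i in seq_len(abs(deficit))) {
      rounded[ord[i]] <- rounded[ord[i]] + sign(deficit)
    }
  }
  list(expected = e, rounded = stats::setNames(as.integer(rounded), names(e)))
}

#' Pearson chi-squared goodness-of-fit test against a segregation ratio
#'
#' Tests observed phenotype-class counts against the class probabilities of a
#' segregation model. Expected counts entering the statistic are the
#' real-valued `n * p_k`, never pre-rounded integers. Degrees of freedom are
#' `k - 1`: the ratio is specified a priori, no parameter is estimated.
#'
#' @param obs Named non-negative integer vector of observed class counts.
#' @param ratio Named per-class probabilities summing to 1; names must cover
#'   those of `obs`.
#' @return List of class `gof_result`: `chi2`, `df`, `p`, `expected`,
#'   `observed`, `n`.
#' @examples
#' m <- segregation_model()
#' chisq_gof(c(BF = 235, GF = 452, WB = 234, WY = 360), enumerate_f2_ratio(m))
#' @export
chisq_gof <- function(obs, ratio) {
  stopifnot(!is.null(names(obs)), !is.null(names(ratio)))
  if (!all(names(obs) %in% names(ratio))) {
    stop("every observed class needs a probability")
  }
  ratio <- ratio[names(obs)]
  if (abs(sum(ratio) - 1) > 1e-8) stop("class probabilities must sum to 1")
  n <- sum(obs)
  e <- n * ratio
  if (any(e <= 0)) stop("all expected counts must be positive")
  chi2 <- sum((obs - e)^2 / e)
  df <- length(obs) - 1L
  structure(
    list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
         expected = e, observed = obs, n = n),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Chi-squared goodness of fit\n")
  tab <- data.frame(observed = as.vector(x$observed),
                    expected = round(as.vector(x$expected), 3),
                    row.names = names(x$observed))
  print(tab)
  cat(sprintf("chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Observed segregation ratio anchored at one class
#'
#' Rescales observed counts so the anchor class equals `anchor_value` (the
#' conventional presentation of segregation ratios, e.g. 3:5.8:3:4.6 anchored
#' at the 3/16 class), rounding half-away-from-zero to `decimals`.
#'
#' @param obs Named observed counts.
#' @param anchor Name of the anchor class (its count must be positive).
#' @param anchor_value Value assigned to the anchor class.
#' @param decimals Decimal places of the reported ratio.
#' @return Named numeric vector of ratio components.
#' @export
observed_ratio <- function(obs, anchor, anchor_value = 3, decimals = 1) {
  stopifnot(!is.null(names(obs)), anchor %in% names(obs))
  if (obs[[anchor]] <= 0) stop("anchor class count must be positive")
  r <- as.numeric(obs) * anchor_value / obs[[anchor]]
  scale <- 10^decimals
  r <- sign(r) * trunc(abs(r) * scale + 0.5) / scale
  stats::setNames(r, names(obs))
}
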