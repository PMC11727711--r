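#' Genomic relationship matrix (kinship) from a dosage matrix
#'
#' Missing genotypes are mean-imputed per variant; each variant is centred by
#' `2 * p_hat` and scaled by `sqrt(2 * p_hat * (1 - p_hat))` (the standard
#' VanRaden-type standardization), and `G = Z Z' / m` over the `m` polymorphic
#' variants. Monomorphic variants are skipped.
#'
#' @param geno Samples x variants dosage matrix (0/1/2/`NA`).
#' @return Symmetric positive semidefinite samples x samples matrix.
#' @export
grm <- function(geno) {
  stopifnot(nrow(geno) >= 2)
  p <- colMeans(geno, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all variants are monomorphic; kinship is undefined")
  g <- geno[, poly, drop = FALSE]
  p <- p[poly]
  # mean imputation, then standardization
  for (j in seq_len(ncol(g))) {
    gj <- g[, j]
    gj[is.na(gj)] <- 2 * p[j]
    g[, j] <- (gj - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  G <- tcrossprod(g) / ncol(g)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  (G + t(G)) / 2
}

#' Principal-component covariates from a kinship matrix
#'
#' Top-`k` eigenvectors of `G`, each scaled by the square root of its
#' eigenvalue. Sign convention: the largest-magnitude loading of each
#' component is made positive, so scores are deterministic.
#'
#' @param G Kinship matrix from [grm()] (or any symmetric PSD matrix).
#' @param k Number of components (default 3; `k = 0` returns an empty
#'   covariate block).
#' @return Samples x `k` score matrix.
#' @export
pca_covariates <- function(G, k = 3) {
  n <- nrow(G)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0) return(matrix(numeric(0), n, 0, dimnames = list(rownames(G), NULL)))
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  sc <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  dimnames(sc) <- list(rownames(G), paste0("PC", seq_len(k)))
  sc
}

# Profiled REML log-likelihood of the null model at a given delta
# (delta = sigma_e2 / sigma_g2), on eigen-rotated data.
reml_profile <- function(delta, d, yr, Xr, logdet_xtx) {
  n <- length(yr); p <- ncol(Xr)
  w <- d + delta
  Xw <- Xr / sqrt(w)
  yw <- yr / sqrt(w)
  xtx <- crossprod(Xw)
  beta <- solve(xtx, crossprod(Xw, yw))
  r <- yw - Xw %*% beta
  rss <- sum(r^2)
  sigma_g2 <- rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sigma_g2) + (n - p) + sum(log(w)) +
            determinant(xtx, logarithm = TRUE)$modulus[1] - logdet_xtx)
}

#' REML fit of the null mixed model y = Xb + g + e, Var(g) = sigma_g2 G
#'
#' Eigendecomposes the kinship matrix once, rotates `y` and `X`, and
#' maximizes the profiled REML log-likelihood over
#' `log10(delta) in [-5, 5]` (`delta = sigma_e2 / sigma_g2`) on a 100-point
#' grid refined by a bounded 1-D optimizer. This is the EMMA-style null fit
#' whose variance components are then reused for every marker test.
#'
#' @param y Numeric phenotype vector, no missing values.
#' @param X Fixed-effect design matrix (intercept, sex, PCs, ...); full
#'   column rank.
#' @param G Kinship matrix; must be PSD up to `-1e-8` relative tolerance.
#' @return Object of class `lmm_fit`: `sigma_g2`, `sigma_e2`, `delta`,
#'   `reml_loglik`, `heritability`, eigen pieces (`eigvals`, `eigvecs`) and
#'   rotated data for reuse by [assoc_scan()]. A near-constant phenotype is
#'   flagged `degenerate`.
#' @export
fit_null_lmm <- function(y, X, G) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n, !anyNA(y))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  e <- eigen(G, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("kinship matrix is not positive semidefinite")
  }
  d <- pmax(e$values, 0)
  yr <- drop(crossprod(e$vectors, y))
  Xr <- crossprod(e$vectors, X)
  logdet_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus[1]

  degenerate <- stats::var(y) < .Machine$double.eps * 100
  if (degenerate) {
    fit <- list(sigma_g2 = 0, sigma_e2 = 0, delta = Inf, reml_loglik = NA_real_)
  } else {
    grid <- seq(-5, 5, length.out = 100)
    ll <- vapply(grid, function(lg) {
      reml_profile(10^lg, d, yr, Xr, logdet_xtx)
    }, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(lg) reml_profile(10^lg, d, yr, Xr, logdet_xtx),
                           c(lo, hi), maximum = TRUE, tol = 1e-8)
    lg <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    delta <- 10^lg
    w <- d + delta
    Xw <- Xr / sqrt(w); yw <- yr / sqrt(w)
    beta <- solve(crossprod(Xw), crossprod(Xw, yw))
    rss <- sum((yw - Xw %*% beta)^2)
    sigma_g2 <- rss / (n - ncol(X))
    fit <- list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                delta = delta,
                reml_loglik = reml_profile(delta, d, yr, Xr, logdet_xtx))
  }
  structure(
    c(fit,
      list(heritability = if (is.finite(fit$delta)) 1 / (1 + fit$delta) else 0,
           eigvals = d, eigvecs = e$vectors, y_rot = yr, X_rot = Xr,
           X = X, y = y, degenerate = degenerate)),
    class = "lmm_fit"
  )
}

#' EMMAX-style association scan
#'
#' Variance components are fixed at the null fit; each variant is tested by
#' generalized least squares on eigen-rotated, variance-whitened data. The
#' default test is the GLS t-test with the residual variance re-estimated per
#' marker (`df = n - p - 1`), which reduces exactly to ordinary linear
#' regression when `G` is the identity; `test = "wald"` instead uses the null
#' fit's genetic variance and refers `beta^2 / se^2` to chi-squared(1).
#' Missing genotypes are mean-imputed per variant. Variants collinear with
#' the covariates (including monomorphic ones) get `NA` results. p-values
#' are floored at 1e-300 so `-log10(p)` stays finite.
#'
#' @param geno Samples x variants dosage matrix.
#' @param variants Variant table aligned with `geno` columns.
#' @param fit Null-model fit from [fit_null_lmm()].
#' @param test `"t"` (default) or `"wald"`.
#' @return Data frame of class `assoc_result`: `chrom`, `pos`, `ref`, `alt`,
#'   `beta`, `se`, `stat`, `p`, `neg_log10_p`.
#' @export
assoc_scan <- function(geno, variants, fit, test = c("t", "wald")) {
  test <- match.arg(test)
  stopifnot(inherits(fit, "lmm_fit"), nrow(geno) == length(fit$y),
            ncol(geno) == nrow(variants))
  n <- length(fit$y)
  w <- fit$eigvals + fit$delta
  if (!is.finite(fit$delta)) w <- fit$eigvals + 1  # degenerate null: unweighted
  sw <- 1 / sqrt(w)
  yw <- fit$y_rot * sw
  Xw <- fit$X_rot * sw
  p_cov <- ncol(Xw)

  # impute, rotate, whiten the genotype block
  Z <- geno
  pm <- colMeans(Z, na.rm = TRUE)
  na <- which(is.na(Z), arr.ind = TRUE)
  if (nrow(na) > 0) Z[na] <- pm[na[, 2]]
  Zw <- crossprod(fit$eigvecs, Z) * sw

  qx <- qr(Xw)
  yr <- qr.resid(qx, yw)
  Zr <- qr.resid(qx, Zw)
  gg <- colSums(Zr^2)
  gy <- colSums(Zr * yr)
  ok <- gg > 1e-10 * n
  beta <- ifelse(ok, gy / gg, NA_real_)
  if (test == "t") {
    rss <- pmax(sum(yr^2) - beta^2 * gg, 0)
    df <- n - p_cov - 1L
    sigma2 <- rss / df
    se <- ifelse(ok, sqrt(sigma2 / gg), NA_real_)
    stat <- beta / se
    p <- 2 * stats::pt(-abs(stat), df)
  } else {
    se <- ifelse(ok, sqrt(fit$sigma_g2 / gg), NA_real_)
    stat <- (beta / se)^2
    p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  p <- pmax(p, 1e-300)
  p[!ok] <- NA_real_
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    beta = beta, se = se, stat = stat, p = p,
    neg_log10_p = -log10(p), stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Bonferroni genome-wide significance threshold on the -log10 scale
#'
#' @param alpha Family-wise error rate in (0, 1) (default 0.01).
#' @param n_snps Number of tests (>= 1).
#' @return `-log10(alpha / n_snps)` at full precision (round to 2 decimals
#'   for presentation; 0.01 / 8,887,194 gives 8.95).
#' @export
bonferroni_threshold <- function(alpha = 0.01, n_snps) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(n_snps >= 1)
  -log10(alpha / n_snps)
}

#' Conditional association re-scan
#'
#' Appends the (mean-imputed) genotype at a conditioning variant to the
#' fixed-effect matrix, refits the null model, and re-runs the scan. The
#' conditioning variant itself is reported with `NA` statistics. This is the
#' mechanism used to remove a major locus's signal (e.g. the beak-locus
#' signal) and expose secondary loci.
#'
#' @param geno,variants As in [assoc_scan()].
#' @param y Phenotype vector.
#' @param X Covariate matrix of the unconditional model.
#' @param G Kinship matrix.
#' @param condition_on Column index of the conditioning variant in `geno`.
#' @param test Passed to [assoc_scan()].
#' @return An `assoc_result` data frame.
#' @export
conditional_scan <- function(geno, variants, y, X, G, condition_on,
                             test = c("t", "wald")) {
  stopifnot(length(condition_on) == 1L, condition_on >= 1,
            condition_on <= ncol(geno))
  g <- geno[, condition_on]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) stop("conditioning variant is monomorphic")
  X2 <- cbind(as.matrix(X), cond = g)
  fit <- fit_null_lmm(y, X2, G)
  res <- assoc_scan(geno, variants, fit, test = match.arg(test))
  res[condition_on, c("beta", "se", "stat", "p", "neg_log10_p")] <- NA_real_
  res
}

#' Build the standard GWAS inputs from a simulated or loaded cohort
#'
#' Convenience wrapper assembling the ordinal phenotype, the fixed-effect
#' matrix (intercept, sex, top-`k` kinship PCs) and the kinship matrix from a
#' genotype matrix plus metadata, using only SNP-type variants.
#'
#' The primary phenotype coding is the ordinal melanin dose
#' `WY = 0, WB = 1, GF = 2, BF = 3` (founder breeds score via their phenotype
#' class). `coding = "feather"` restricts to black-beaked classes
#' (`WB = 0, GF = 1, BF = 2`, others `NA`) for the feather-locus fine scan.
#'
#' @param geno Samples x variants dosage matrix.
#' @param variants Variant table.
#' @param metadata Data frame with `phenotype` and `sex` columns, rows
#'   aligned with `geno`.
#' @param k_pcs Number of PC covariates (default 3).
#' @param coding `"ordinal"` (default) or `"feather"`.
#' @return List: `y`, `X`, `G`, `keep` (sample mask), `snp_cols` (variant
#'   mask used for the kinship/PCs), plus the subset `geno`/`variants`.
#' @export
gwas_inputs <- function(geno, variants, metadata, k_pcs = 3,
                        coding = c("ordinal", "feather")) {
  coding <- match.arg(coding)
  stopifnot(nrow(metadata) == nrow(geno))
  y_map <- switch(coding,
    ordinal = c(WY = 0, WB = 1, GF = 2, BF = 3),
    feather = c(WB = 0, GF = 1, BF = 2)
  )
  y <- unname(y_map[metadata$phenotype])
  keep <- !is.na(y)
  snp_cols <- variants$vtype == "SNP" & !variants$multiallelic
  g <- geno[keep, snp_cols, drop = FALSE]
  G <- grm(g)
  pcs <- pca_covariates(G, k_pcs)
  sex <- as.numeric(metadata$sex[keep] == "M")
  X <- cbind(intercept = 1, sex = sex, pcs)
  list(y = y[keep], X = X, G = G, keep = keep, snp_cols = snp_cols,
       geno = g, variants = variants[snp_cols, , drop = FALSE])
}
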