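# builds the founder-contrast divergence table for a cohort
founder_div <- function(coh) {
  divergence_table(coh$geno, coh$variants,
                   which(coh$metadata$breed == "LC"),
                   which(coh$metadata$breed == "PK"))
}

test_that("informative-SNP selection applies the delta-AF screen in-region", {
  cfg <- finemap_config(seed = 301)
  coh <- breed_cross(cfg)
  info <- informative_snps(founder_div(coh), finemap_region())
  expect_equal(nrow(info), 36L)  # engineered fixture: exactly 36 markers
  expect_true(all(info$delta_af > 0.8))
  expect_true(all(diff(info$pos) > 0))
  # the planted causal SNP (fixed difference) is included
  expect_true(5303994 %in% info$pos)
  # a half-diverged SNP is excluded
  div <- founder_div(coh)
  div$delta_af[div$pos == 5303994] <- 0.5
  info2 <- informative_snps(div, finemap_region())
  expect_false(5303994 %in% info2$pos)
  # empty result warns
  expect_warning(informative_snps(div[0, ], finemap_region()), "no informative")
})

test_that("ancestry painting recovers generation structure and crossovers", {
  cfg <- finemap_config(seed = 302, n_f2 = 80)
  coh <- breed_cross(cfg)
  info <- informative_snps(founder_div(coh), finemap_region())
  path <- infer_ancestry(coh$geno, coh$variants, info)
  meta <- coh$metadata
  # founders are uniformly homozygous for their own ancestry
  expect_true(all(path$states[meta$breed == "LC", ] == "HOM_P1"))
  expect_true(all(path$states[meta$breed == "PK", ] == "HOM_P2"))
  # every F1 is heterozygous at every informative SNP
  expect_true(all(path$states[meta$generation == "F1", ] == "HET"))

  # an F2 with exactly one crossover in the region switches state once
  bps <- find_breakpoints(path)
  region <- finemap_region()
  n_co_region <- vapply(meta$sample_id, function(s) {
    co <- coh$truth$crossovers[[s]]
    if (is.null(co)) return(0L)
    sum(vapply(co, function(df) {
      sum(df$chrom == region$chrom & df$pos >= min(info$pos) &
            df$pos <= max(info$pos))
    }, numeric(1)))
  }, numeric(1))
  one <- names(n_co_region)[n_co_region == 1 & meta$generation == "F2"]
  if (length(one) > 0) {
    for (s in one) expect_equal(sum(bps$sample_id == s), 1L)
  }
})

test_that("breakpoint detection is exact on noise-free paths", {
  # hand-built path: HOM_P1 x3, UNKNOWN, HET x2 -> one breakpoint spanning
  # the unknown gap, between the flanking known SNPs
  states <- matrix(c("HOM_P1", "HOM_P1", "HOM_P1", "UNKNOWN", "HET", "HET"),
                   nrow = 1, dimnames = list("s1", NULL))
  path <- structure(list(chrom = "chr2", pos = c(10, 20, 30, 40, 50, 60),
                         states = states), class = "ancestry_path")
  bp <- find_breakpoints(path)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$left, 30)
  expect_equal(bp$right, 50)
  expect_equal(c(bp$from, bp$to), c("HOM_P1", "HET"))
  # uniform path: none
  path$states[] <- "HET"
  expect_equal(nrow(find_breakpoints(path)), 0L)
})

test_that("block partitioning cuts at the union of breakpoint intervals", {
  pos <- seq(100, 1000, by = 100)
  mk_path <- function(mat) structure(list(chrom = "chr2", pos = pos,
                                          states = mat),
                                     class = "ancestry_path")
  # two individuals, breakpoints in gaps 2-3 and 7-8 -> 4 distinct cuts? no: 2
  m <- rbind(
    s1 = c(rep("HOM_P1", 2), rep("HET", 8)),
    s2 = c(rep("HET", 7), rep("HOM_P2", 3))
  )
  path <- mk_path(m)
  bps <- find_breakpoints(path)
  blocks <- partition_blocks(path, bps)
  expect_equal(nrow(blocks$blocks), 3L)  # 2 cut gaps -> 3 blocks
  expect_equal(blocks$states["s1", ], c(block1 = "HOM_P1", block2 = "HET",
                                        block3 = "HET"))
  # no breakpoints -> a single block spanning the region's SNPs
  path0 <- mk_path(matrix(rep("HET", 10), 1, dimnames = list("a", NULL)))
  b0 <- partition_blocks(path0, find_breakpoints(path0))
  expect_equal(nrow(b0$blocks), 1L)
  expect_equal(c(b0$blocks$start, b0$blocks$end), c(100, 1000))
  # 4 distinct cut gaps -> 5 blocks
  m4 <- rbind(
    a = c("HOM_P1", rep("HET", 9)),
    b = c(rep("HET", 3), rep("HOM_P1", 7)),
    c = c(rep("HOM_P2", 5), rep("HET", 5)),
    d = c(rep("HET", 8), rep("HOM_P2", 2))
  )
  p4 <- mk_path(m4)
  b4 <- partition_blocks(p4, find_breakpoints(p4))
  expect_equal(nrow(b4$blocks), 5L)
})

test_that("block-phenotype concordance flags the causal block", {
  cfg <- finemap_config(seed = 303, n_f2 = 200)
  coh <- breed_cross(cfg)
  info <- informative_snps(founder_div(coh), finemap_region())
  path <- infer_ancestry(coh$geno, coh$variants, info)
  # score on intercross individuals only (founders' beak genotypes differ)
  f12 <- coh$metadata$generation %in% c("F1", "F2")
  path$states <- path$states[f12, , drop = FALSE]
  bps <- find_breakpoints(path)
  blocks <- partition_blocks(path, bps)
  conc <- block_concordance(blocks, coh$metadata$phenotype[f12])
  causal_pos <- 5303994
  in_block <- conc$start <= causal_pos & conc$end >= causal_pos
  expect_true(any(in_block))
  expect_equal(conc$concordance[in_block], 1)
  expect_true(conc$candidate[in_block])
  # a cohort of F1s only is degenerate: every block scores 1
  f1 <- coh$metadata$generation == "F1"
  path1 <- infer_ancestry(coh$geno, coh$variants, info)
  path1$states <- path1$states[f1, , drop = FALSE]
  b1 <- partition_blocks(path1, find_breakpoints(path1))
  c1 <- block_concordance(b1, coh$metadata$phenotype[f1])
  expect_true(all(c1$concordance == 1))
  expect_error(block_concordance(blocks, rep("WY", nrow(blocks$states))),
               "black-beaked")
})

test_that("LD r2 has its algebraic fixed points and null behaviour", {
  set.seed(71)
  g <- rbinom(1000, 2, 0.5)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)  # affine invariance
  h <- rbinom(1000, 2, 0.5)
  expect_lt(ld_r2(g, h), 0.02)     # independent vectors
  expect_true(is.na(ld_r2(g, rep(1, 1000))))
})

test_that("the three-step screen recovers exactly the planted causal SNPs", {
  # engineered region: LC/PK/MD/PT/BF populations, 1 causal SNP + its
  # complete-LD partner + 1 causal-like indel + 30 decoys with high LC-PK
  # FST but discordant genotypes in the validation populations
  set.seed(404)
  n_per <- c(LC = 25, PK = 25, MD = 12, PT = 6, BF = 10)
  breeds <- rep(names(n_per), n_per)
  n <- length(breeds)
  m <- 33
  pos <- sort(sample(5240000:5320000, m))
  variants <- data.frame(
    chrom = "chr33", pos = pos, id = NA_character_, ref = "A", alt = "G",
    vtype = "SNP", multiallelic = FALSE, stringsAsFactors = FALSE
  )
  ic <- 1L; ild <- 2L; iindel <- 3L
  variants$vtype[iindel] <- "indel"
  variants$ref[iindel] <- "AT"
  geno <- matrix(0L, n, m, dimnames = list(paste0(breeds, seq_len(n)), NULL))
  # causal: fixed ref (rr) in LC, fixed alt (RR) in every black breed + PK
  geno[, ic] <- ifelse(breeds == "LC", 0L, 2L)
  geno[, ild] <- geno[, ic]                  # complete LD partner
  geno[, iindel] <- geno[, ic]               # concordant but an indel
  # decoys: fixed LC-vs-PK difference, polymorphic in the validation breeds
  for (j in 4:m) {
    g <- ifelse(breeds == "LC", 0L, 2L)
    val <- breeds %in% c("MD", "PT")
    g[val] <- rbinom(sum(val), 2, 0.5)
    geno[, j] <- g
  }
  pops <- split(seq_len(n), breeds)
  fdiv <- divergence_table(geno, variants, pops$LC, pops$PK)
  bdivs <- list(MD = divergence_table(geno, variants, pops$LC, pops$MD),
                PT = divergence_table(geno, variants, pops$LC, pops$PT),
                BF = divergence_table(geno, variants, pops$LC, pops$BF))
  val_samples <- c(pops$MD, pops$PT)
  rep <- causative_screen(variants, geno, fdiv, bdivs,
                          validation_samples = val_samples,
                          validation_phenotype = rep("BF", length(val_samples)))
  # nesting invariant
  expect_true(all(rep$step3 <= rep$step2) && all(rep$step2 <= rep$step1))
  # the planted indel is excluded up front, reported separately
  expect_equal(rep$excluded_indels, iindel)
  expect_false(iindel %in% rep$final)
  # exactly the causal SNP and its complete-LD partner survive, as one group
  expect_setequal(rep$final, c(ic, ild))
  expect_length(rep$ld_groups, 1L)
  expect_setequal(rep$ld_groups[[1]], c(ic, ild))
  expect_output(print(rep), "final candidates")

  # empty survivors at a step is a report, not an error
  rep2 <- causative_screen(variants, geno, fdiv, bdivs,
                           validation_samples = val_samples,
                           validation_phenotype = rep("BF", length(val_samples)),
                           fst_min = 1.1)
  expect_length(rep2$final, 0L)
  expect_error(causative_screen(variants, geno, fdiv, bdivs,
                                validation_samples = integer(0),
                                validation_phenotype = character(0)),
               "empty")
})
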