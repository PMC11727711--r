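test_that("layout and panel constructors enforce their invariants", {
  expect_error(genome_layout("chr1", 100, list(chr1 = c(5, 5, 9))),
               "strictly increasing")
  expect_error(genome_layout("chr1", 100, list(chr1 = c(5, 200))),
               "within")
  layout <- tiny_layout()
  expect_equal(layout$n_snps, 6L)
  # frequencies outside [0, 1] rejected
  expect_error(founder_panel(layout, rep(1.2, 6), rep(0.5, 6),
                             causal_b = list(chrom = "chr1", pos = 5e6),
                             causal_r = list(chrom = "chr2", pos = 5e6)),
               "\\[0, 1\\]")
  # causal loci must be fixed for opposite alleles
  f1 <- c(0.5, 0.9, 0.3, 0.6, 0, 0.4); f2 <- c(0.5, 0, 0.3, 0.6, 1, 0.4)
  expect_error(founder_panel(layout, f1, f2,
                             causal_b = list(chrom = "chr1", pos = 5e6),
                             causal_r = list(chrom = "chr2", pos = 5e6)),
               "fixed for opposite alleles")
  # ... and on different chromosomes
  layout1 <- genome_layout("chr1", 1e7, list(chr1 = c(2e6, 5e6, 8e6)))
  expect_error(founder_panel(layout1, c(0.5, 1, 0), c(0.5, 0, 1),
                             causal_b = list(chrom = "chr1", pos = 5e6),
                             causal_r = list(chrom = "chr1", pos = 8e6)),
               "different chromosomes")
  # a layout with zero SNPs is unusable
  layout0 <- genome_layout(c("chr1", "chr2"), c(1e7, 1e7),
                           list(chr1 = numeric(), chr2 = numeric()))
  expect_error(founder_panel(layout0, numeric(), numeric(),
                             causal_b = list(chrom = "chr1", pos = 5e6),
                             causal_r = list(chrom = "chr2", pos = 5e6)),
               "zero SNPs")
})

test_that("founder simulation matches its binomial sampling model", {
  cfg <- tiny_config(seed = 3, n_per_founder = 50, n_f1 = 0, n_f2 = 0)
  coh <- simulate_founders(cfg)
  expect_equal(nrow(coh$geno), 100L)
  lc <- coh$metadata$breed == "LC"
  pk <- coh$metadata$breed == "PK"
  ib <- coh$truth$causal$index[coh$truth$causal$locus == "B"]
  ir <- coh$truth$causal$index[coh$truth$causal$locus == "R"]
  # causal loci homozygous for the breed-fixed allele in every founder
  expect_true(all(coh$geno[lc, ib] == 2) && all(coh$geno[pk, ib] == 0))
  expect_true(all(coh$geno[lc, ir] == 0) && all(coh$geno[pk, ir] == 2))
  # freq-0.5 SNP: mean genotype within 3 binomial SDs of 1.0 (n = 50)
  sd3 <- 3 * sqrt(2 * 0.5 * 0.5 / 50)
  expect_lt(abs(mean(coh$geno[lc, 1]) - 1), sd3)
  # freq-0 side of a fixed SNP: all genotypes 0
  expect_true(all(coh$geno[pk, ib] == 0))
})

test_that("gametes follow the Haldane crossover model", {
  layout <- tiny_layout(recomb_rate = 0)
  h1 <- rep(0L, 6); h2 <- rep(1L, 6)
  set.seed(1)
  g <- make_gamete(h1, h2, layout)
  # no recombination: each chromosome is an intact parental haplotype
  for (ci in 1:2) {
    idx <- layout$index[[ci]]
    expect_true(all(g$allele[idx] == 0) || all(g$allele[idx] == 1))
  }
  expect_equal(nrow(g$crossovers), 0L)

  # single-SNP chromosome: the gamete allele is one of the parental alleles
  l1 <- genome_layout("chr1", 1e6, list(chr1 = 5e5), recomb_rate = 2)
  set.seed(2)
  g1 <- make_gamete(0L, 1L, l1)
  expect_true(g1$allele %in% 0:1)

  # 1 cM/Mb on a 100-Mb chromosome: mean crossover count ~= 1 Morgan
  l2 <- genome_layout("chrA", 1e8, list(chrA = c(1, 1e8)), recomb_rate = 1)
  set.seed(3)
  n_x <- replicate(10000, nrow(make_gamete(c(0L, 0L), c(1L, 1L), l2)$crossovers))
  expect_lt(abs(mean(n_x) - 1), 3 * sqrt(1 / 10000))  # Poisson(1) SE bound
})

test_that("the intercross has the published structure", {
  cfg <- tiny_config(seed = 11, n_f2 = 200)
  coh <- breed_cross(cfg)
  f1 <- coh$metadata$generation == "F1"
  # every F1 is doubly heterozygous and grey-feathered
  dip <- coh$truth$diplotypes
  expect_true(all(dip$b_count[f1] == 1 & dip$r_count[f1] == 1))
  expect_true(all(coh$metadata$phenotype[f1] == "GF"))
  # phenotype equals the map applied to the true causal diplotypes, everywhere
  expect_equal(coh$metadata$phenotype,
               phenotype_of(coh$model, dip$b_count, dip$r_count))
  # n_f2 = 0 leaves founders and F1 only
  coh0 <- breed_cross(tiny_config(seed = 11, n_f2 = 0))
  expect_setequal(unique(coh0$metadata$generation), c("P0", "F1"))
  expect_error(cross_config(tiny_layout(), tiny_panel(), n_f1 = 0, n_f2 = 10),
               "without F1")
})

test_that("a fixed seed reproduces the cohort exactly and crossovers stay in bounds", {
  cfg <- tiny_config(seed = 42, n_f2 = 60, missing_rate = 0.05)
  a <- breed_cross(cfg)
  b <- breed_cross(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$crossovers, b$truth$crossovers)
  lens <- stats::setNames(a$layout$chrom$length, a$layout$chrom$name)
  for (co in a$truth$crossovers) {
    if (is.null(co)) next
    for (df in co) {
      if (nrow(df) > 0) expect_true(all(df$pos > 0 & df$pos < lens[df$chrom]))
    }
  }
})

test_that("every F2 allele traces back to one founder haplotype", {
  cfg <- tiny_config(seed = 5, n_f2 = 40)
  coh <- breed_cross(cfg)
  tr <- coh$truth
  n_founders <- 2 * cfg$n_per_founder
  founder_hap <- rbind(tr$hap_a[seq_len(n_founders), ],
                       tr$hap_b[seq_len(n_founders), ])
  # founder haplotype id 2i-1 is founder i's hap_a, 2i its hap_b
  hap_of <- function(id, v) {
    i <- ceiling(id / 2)
    if (id %% 2 == 1) tr$hap_a[i, v] else tr$hap_b[i, v]
  }
  f2 <- which(coh$metadata$generation == "F2")
  traced <- vapply(f2, function(i) {
    all(vapply(seq_len(ncol(coh$geno)), function(v) {
      tr$hap_a[i, v] == hap_of(tr$origin_a[i, v], v) &&
        tr$hap_b[i, v] == hap_of(tr$origin_b[i, v], v)
    }, logical(1)))
  }, logical(1))
  expect_true(all(traced))
})

test_that("large F2 cohorts segregate 3:6:3:4 and zero recombination keeps founder haplotypes intact", {
  cfg <- tiny_config(seed = 9, n_per_founder = 10, n_f1 = 30, n_f2 = 4000)
  coh <- breed_cross(cfg)
  f2 <- coh$metadata$generation == "F2"
  obs <- table(factor(coh$metadata$phenotype[f2],
                      levels = c("BF", "GF", "WB", "WY")))
  p <- c(3, 6, 3, 4) / 16
  # within 3 multinomial SEs per class
  se3 <- 3 * sqrt(p * (1 - p) / 4000)
  expect_true(all(abs(as.vector(obs) / 4000 - p) < se3))

  # recomb_rate = 0: every F2 chromosome is an intact founder haplotype
  cfg0 <- tiny_config(seed = 10, n_f2 = 30, recomb_rate = 0)
  coh0 <- breed_cross(cfg0)
  for (i in which(coh0$metadata$generation == "F2")) {
    for (idx in coh0$layout$index) {
      expect_length(unique(coh0$truth$origin_a[i, idx]), 1L)
      expect_length(unique(coh0$truth$origin_b[i, idx]), 1L)
    }
  }
})

test_that("simulated depth reflects planted copy numbers", {
  cfg <- tiny_config(seed = 13, n_per_founder = 15, n_f1 = 0, n_f2 = 0)
  coh <- simulate_founders(cfg)
  cnvs <- data.frame(
    chrom = c("chr1", "chr1"), start = c(2e6, 6e6), end = c(2.5e6, 6.5e6),
    breed = c("LC", "LC"), copies = c(0, 3), stringsAsFactors = FALSE
  )
  set.seed(99)
  dp <- simulate_depth(coh, cnvs, window_bp = 1e5, mean_depth = 40)
  lc <- coh$metadata$breed == "LC"
  del <- dp$windows$chrom == "chr1" & dp$windows$start >= 2e6 &
    dp$windows$end <= 2.5e6
  dup <- dp$windows$chrom == "chr1" & dp$windows$start >= 6e6 &
    dp$windows$end <= 6.5e6
  base <- !del & !dup
  expect_equal(mean(dp$counts[del, lc]), 0)                     # homozygous loss
  expect_equal(mean(dp$counts[dup, lc]) / 40, 1.5, tolerance = 0.05)
  expect_equal(mean(dp$counts[base, lc]) / 40, 1, tolerance = 0.02)
  expect_error(simulate_depth(coh, window_bp = 0), "positive")
  bad <- data.frame(chrom = "chrX", start = 1, end = 10, breed = "LC",
                    copies = 1)
  expect_error(simulate_depth(coh, bad), "outside")
})

test_that("cohorts round-trip through the on-disk formats", {
  cfg <- tiny_config(seed = 21, n_per_founder = 5, n_f1 = 10, n_f2 = 15,
                     missing_rate = 0.1)
  coh <- breed_cross(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  rt <- read_vcf(paths[["vcf"]])
  expect_equal(rt$variants$chrom, coh$variants$chrom)
  expect_equal(rt$variants$pos, coh$variants$pos)
  expect_equal(unname(rt$geno), unname(coh$geno))
  meta <- read.delim(paths[["metadata"]], stringsAsFactors = FALSE)
  expect_equal(meta$sample_id, coh$metadata$sample_id)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$causal$pos, coh$truth$causal$pos)

  set.seed(1)
  dp <- simulate_depth(coh, window_bp = 1e6, mean_depth = 10)
  f <- file.path(dir, "depth.tsv")
  write_depth(dp, f)
  dp2 <- read_depth(f)
  expect_equal(dp2$counts, dp$counts)
  expect_equal(dp2$windows$start, dp$windows$start)
})
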