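#' Genome layout for the intercross simulator
#'
#' Describes the simulated genome: chromosome names and lengths, the 1-based
#' SNP positions on each chromosome (VCF convention), and a genome-wide
#' recombination rate in centimorgans per megabase.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @param snp_pos Named list (one entry per chromosome) of strictly increasing
#'   1-based SNP positions.
#' @param recomb_rate Recombination rate, cM/Mb (>= 0). The crossover model
#'   is Haldane's: per-meiosis crossover counts are Poisson in the chromosome
#'   map length, positions uniform, no interference.
#' @return Object of class `genome_layout` with an `index` element giving
#'   each chromosome's variant indices in the flattened variant order.
#' @export
genome_layout <- function(chrom, length, snp_pos, recomb_rate = 1) {
  stopifnot(base::length(chrom) == base::length(length),
            base::length(chrom) == base::length(snp_pos),
            all(length > 0), recomb_rate >= 0)
  snp_pos <- lapply(snp_pos, as.numeric)
  for (i in seq_along(chrom)) {
    p <- snp_pos[[i]]
    if (base::length(p) > 0 &&
        (any(diff(p) <= 0) || p[1] < 1 || p[base::length(p)] > length[i])) {
      stop("SNP positions must be strictly increasing and within [1, length] ",
           "on chromosome ", chrom[i])
    }
  }
  n_per <- vapply(snp_pos, base::length, integer(1))
  ends <- cumsum(n_per)
  index <- Map(function(e, n) if (n > 0) seq.int(e - n + 1L, e) else integer(),
               ends, n_per)
  names(snp_pos) <- names(index) <- chrom
  structure(
    list(chrom = data.frame(name = chrom, length = as.numeric(length),
                            stringsAsFactors = FALSE),
         snp = snp_pos, index = index, n_snps = sum(n_per),
         recomb_rate = recomb_rate),
    class = "genome_layout"
  )
}

#' Founder panel: breed allele frequencies and the two planted causal loci
#'
#' Holds per-breed alternate-allele frequencies for every variant in the
#' layout plus the coordinates of the two causal loci. The alt allele at the
#' melanin-synthesis locus is the `B` allele (fixed in breed 1, the
#' Liancheng-like `BBrr` founder); the alt allele at the feather-deposition
#' locus is the `R` allele (fixed in breed 2, the Pekin-like `bbRR` founder).
#' Both causal loci must be fixed for opposite alleles (delta-AF = 1) and lie
#' on different chromosomes.
#'
#' @param layout A [genome_layout()].
#' @param freq1,freq2 Alt-allele frequencies in breed 1 / breed 2, one value
#'   per variant in flattened layout order, each in `[0, 1]`.
#' @param causal_b,causal_r `list(chrom =, pos =)` of the two causal loci;
#'   positions must be SNPs of the layout.
#' @param breed_names Labels of the two founder breeds.
#' @param vtype Optional per-variant type vector (`"SNP"`/`"indel"`),
#'   default all `"SNP"`.
#' @return Object of class `founder_panel` with a `variants` data.frame.
#' @export
founder_panel <- function(layout, freq1, freq2, causal_b, causal_r,
                          breed_names = c("LC", "PK"), vtype = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  m <- layout$n_snps
  if (m == 0L) stop("layout has zero SNPs")
  stopifnot(length(freq1) == m, length(freq2) == m)
  if (any(freq1 < 0 | freq1 > 1 | freq2 < 0 | freq2 > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (is.null(vtype)) vtype <- rep("SNP", m)
  chrom <- rep(layout$chrom$name, vapply(layout$snp, length, integer(1)))
  pos <- unlist(layout$snp, use.names = FALSE)
  variants <- data.frame(
    chrom = chrom, pos = as.integer(pos), id = NA_character_,
    ref = ifelse(vtype == "SNP", "A", "AT"), alt = "G",
    vtype = vtype, multiallelic = FALSE, stringsAsFactors = FALSE
  )
  locus_index <- function(l) {
    i <- which(chrom == l$chrom & pos == l$pos)
    if (length(i) != 1L) stop("causal locus ", l$chrom, ":", l$pos,
                              " is not a unique layout SNP")
    i
  }
  ib <- locus_index(causal_b)
  ir <- locus_index(causal_r)
  if (causal_b$chrom == causal_r$chrom) {
    stop("the two causal loci must lie on different chromosomes")
  }
  # B fixed (alt) in breed 1, absent in breed 2; R the reverse
  if (!(freq1[ib] == 1 && freq2[ib] == 0 && freq1[ir] == 0 && freq2[ir] == 1)) {
    stop("causal loci must be fixed for opposite alleles in the two breeds ",
         "(freq1/freq2 = 1/0 at the B locus and 0/1 at the R locus)")
  }
  structure(
    list(breed_names = breed_names, freq = rbind(freq1, freq2),
         causal_b = causal_b, causal_r = causal_r,
         causal_index = c(B = ib, R = ir), variants = variants),
    class = "founder_panel"
  )
}

#' Cross design: cohort sizes, missingness and seed
#'
#' @param layout A [genome_layout()].
#' @param founders A [founder_panel()].
#' @param n_per_founder Founder individuals simulated per breed.
#' @param n_f1,n_f2 F1 and F2 cohort sizes.
#' @param missing_rate Per-genotype i.i.d. missingness fraction in `[0, 1)`.
#' @param seed RNG seed; a fixed seed makes the simulated cohort
#'   byte-identical across runs.
#' @param model Segregation model used to assign phenotypes
#'   (default [segregation_model()]).
#' @return Object of class `cross_config`.
#' @export
cross_config <- function(layout, founders, n_per_founder = 30, n_f1 = 60,
                         n_f2 = 320, missing_rate = 0, seed = 1,
                         model = segregation_model()) {
  stopifnot(inherits(layout, "genome_layout"), inherits(founders, "founder_panel"),
            n_per_founder >= 0, n_f1 >= 0, n_f2 >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (n_f2 > 0 && n_f1 == 0) stop("cannot breed an F2 cohort without F1 parents")
  if (n_f1 > 0 && n_per_founder == 0) stop("cannot breed F1 without founders")
  structure(
    list(layout = layout, founders = founders,
         n_per_founder = as.integer(n_per_founder), n_f1 = as.integer(n_f1),
         n_f2 = as.integer(n_f2), missing_rate = missing_rate,
         seed = as.integer(seed), model = model),
    class = "cross_config"
  )
}

#' Draw one gamete from a phased parent diplotype
#'
#' Haldane crossover model: per chromosome the crossover count is Poisson in
#' the chromosome's map length (bp x cM/Mb, converted to Morgans), crossover
#' positions are uniform in bp, and the gamete alternates between the two
#' parental haplotypes at the breakpoints, starting from a random haplotype.
#' With `recomb_rate = 0` the gamete is an intact copy of one parental
#' haplotype. Uses the current RNG state.
#'
#' @param hap1,hap2 The parent's two haplotypes: 0/1 allele vectors over the
#'   layout's flattened SNP order.
#' @param layout A [genome_layout()].
#' @return List: `allele` (gamete allele vector), `from` (1/2, source
#'   haplotype per SNP), `crossovers` (data.frame `chrom`, `pos` of the
#'   crossover positions, possibly empty).
#' @export
make_gamete <- function(hap1, hap2, layout) {
  stopifnot(length(hap1) == layout$n_snps, length(hap2) == layout$n_snps)
  from <- integer(layout$n_snps)
  co_chrom <- character(0)
  co_pos <- numeric(0)
  for (ci in seq_len(nrow(layout$chrom))) {
    idx <- layout$index[[ci]]
    len <- layout$chrom$length[ci]
    morgans <- len * layout$recomb_rate / 1e8  # bp * cM/Mb -> Morgans
    k <- if (morgans > 0) stats::rpois(1L, morgans) else 0L
    bp <- if (k > 0) sort(stats::runif(k, 0, len)) else numeric(0)
    start <- sample.int(2L, 1L)
    if (length(idx) > 0) {
      seg <- findInterval(layout$snp[[ci]], bp)
      from[idx] <- 1L + (start - 1L + seg) %% 2L
    }
    if (k > 0) {
      co_chrom <- c(co_chrom, rep(layout$chrom$name[ci], k))
      co_pos <- c(co_pos, bp)
    }
  }
  allele <- ifelse(from == 1L, hap1, hap2)
  list(allele = allele, from = from,
       crossovers = data.frame(chrom = co_chrom, pos = co_pos,
                               stringsAsFactors = FALSE))
}

# Founder simulation shared by simulate_founders() and breed_cross();
# assumes the RNG has been seeded by the caller.
sim_founders_impl <- function(config) {
  layout <- config$layout
  fp <- config$founders
  m <- layout$n_snps
  n <- config$n_per_founder
  n_tot <- 2L * n
  hap_a <- matrix(0L, n_tot, m)
  hap_b <- matrix(0L, n_tot, m)
  breed <- rep(fp$breed_names, each = n)
  for (i in seq_len(n_tot)) {
    f <- fp$freq[if (i <= n) 1L else 2L, ]
    hap_a[i, ] <- stats::rbinom(m, 1L, f)
    hap_b[i, ] <- stats::rbinom(m, 1L, f)
  }
  # global founder-haplotype ids: founder i contributes ids 2i-1 and 2i
  origin_a <- matrix(rep(2L * seq_len(n_tot) - 1L, m), n_tot, m)
  origin_b <- matrix(rep(2L * seq_len(n_tot), m), n_tot, m)
  ids <- sprintf("%s%03d", breed, c(seq_len(n), seq_len(n)))
  list(hap_a = hap_a, hap_b = hap_b, origin_a = origin_a, origin_b = origin_b,
       breed = breed, ids = ids)
}

finalize_cohort <- function(config, hap_a, hap_b, origin_a, origin_b,
                            ids, breed, generation, crossovers) {
  fp <- config$founders
  rownames(hap_a) <- rownames(hap_b) <- ids
  geno <- hap_a + hap_b
  b_count <- geno[, fp$causal_index["B"]]
  r_count <- geno[, fp$causal_index["R"]]
  phenotype <- phenotype_of(config$model, b_count, r_count)
  sex <- c("F", "M")[stats::rbinom(length(ids), 1L, 0.5) + 1L]
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_integer_
  }
  colnames(geno) <- paste0(fp$variants$chrom, ":", fp$variants$pos)
  metadata <- data.frame(
    sample_id = ids, breed = breed, generation = generation,
    phenotype = phenotype, sex = sex, stringsAsFactors = FALSE
  )
  truth <- list(
    causal = data.frame(
      locus = c("B", "R"),
      chrom = c(fp$causal_b$chrom, fp$causal_r$chrom),
      pos = c(fp$causal_b$pos, fp$causal_r$pos),
      index = unname(fp$causal_index), stringsAsFactors = FALSE
    ),
    diplotypes = data.frame(sample_id = ids, b_count = unname(b_count),
                            r_count = unname(r_count),
                            stringsAsFactors = FALSE),
    crossovers = crossovers,
    hap_a = hap_a, hap_b = hap_b,
    origin_a = origin_a, origin_b = origin_b
  )
  structure(
    list(variants = fp$variants, geno = geno, metadata = metadata,
         truth = truth, layout = config$layout, model = config$model),
    class = "sim_cohort"
  )
}

#' Simulate the two founder breeds only
#'
#' Founder genotypes are drawn per breed as two Bernoulli haplotypes per
#' individual (so genotypes are Binomial(2, freq)); at the causal loci every
#' founder is homozygous for its breed-fixed allele by construction.
#'
#' @param config A [cross_config()].
#' @return A `sim_cohort` (see [breed_cross()] for the structure).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  f <- sim_founders_impl(config)
  finalize_cohort(config, f$hap_a, f$hap_b, f$origin_a, f$origin_b,
                  f$ids, f$breed, rep("P0", length(f$ids)),
                  stats::setNames(rep(list(NULL), length(f$ids)), f$ids))
}

#' Simulate a full founder / F1 / F2 intercross cohort
#'
#' Breed-1 x breed-2 matings produce each F1 individual (one gamete from a
#' random founder of each breed); every F1 is heterozygous at both causal
#' loci and phenotypically grey-feathered under the default model. Each F2
#' individual is formed from two independent F1 gametes (two distinct F1
#' parents whenever possible). Phenotypes are assigned by applying the
#' segregation model to the true causal diplotypes; crossover positions and
#' founder-haplotype origins of every transmitted allele are recorded in
#' `truth`.
#'
#' @param config A [cross_config()]. The same config (including seed) always
#'   reproduces the identical cohort.
#' @return A `sim_cohort`: list with `variants`, `geno` (samples x variants,
#'   `NA` = missing), `metadata` (sample_id, breed, generation, phenotype,
#'   sex), `truth` (causal loci, per-sample causal diplotypes, per-gamete
#'   crossovers, haplotypes and founder-haplotype origins), `layout`,
#'   `model`.
#' @export
breed_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  set.seed(config$seed)
  fd <- sim_founders_impl(config)
  m <- config$layout$n_snps
  n_fnd <- length(fd$ids)
  n_lc <- config$n_per_founder

  n_all <- n_fnd + config$n_f1 + config$n_f2
  hap_a <- matrix(0L, n_all, m); hap_a[seq_len(n_fnd), ] <- fd$hap_a
  hap_b <- matrix(0L, n_all, m); hap_b[seq_len(n_fnd), ] <- fd$hap_b
  origin_a <- matrix(0L, n_all, m); origin_a[seq_len(n_fnd), ] <- fd$origin_a
  origin_b <- matrix(0L, n_all, m); origin_b[seq_len(n_fnd), ] <- fd$origin_b
  ids <- c(fd$ids, sprintf("F1_%03d", seq_len(config$n_f1)),
           sprintf("F2_%03d", seq_len(config$n_f2)))
  breed <- c(fd$breed, rep("F1", config$n_f1), rep("F2", config$n_f2))
  generation <- c(rep("P0", n_fnd), rep("F1", config$n_f1),
                  rep("F2", config$n_f2))
  crossovers <- stats::setNames(rep(list(NULL), n_all), ids)

  draw_from <- function(parent_row) {
    g <- make_gamete(hap_a[parent_row, ], hap_b[parent_row, ], config$layout)
    g$origin <- ifelse(g$from == 1L, origin_a[parent_row, ],
                       origin_b[parent_row, ])
    g
  }
  f1_rows <- integer(0)
  for (i in seq_len(config$n_f1)) {
    row <- n_fnd + i
    dam <- sample.int(n_lc, 1L)                 # breed-1 founder
    sire <- n_lc + sample.int(n_lc, 1L)         # breed-2 founder
    ga <- draw_from(dam); gb <- draw_from(sire)
    hap_a[row, ] <- ga$allele; origin_a[row, ] <- ga$origin
    hap_b[row, ] <- gb$allele; origin_b[row, ] <- gb$origin
    crossovers[[row]] <- list(maternal = ga$crossovers, paternal = gb$crossovers)
    f1_rows <- c(f1_rows, row)
  }
  for (i in seq_len(config$n_f2)) {
    row <- n_fnd + config$n_f1 + i
    if (config$n_f1 >= 2L) {
      pr <- sample(f1_rows, 2L)
    } else {
      pr <- c(f1_rows, f1_rows)
    }
    ga <- draw_from(pr[1]); gb <- draw_from(pr[2])
    hap_a[row, ] <- ga$allele; origin_a[row, ] <- ga$origin
    hap_b[row, ] <- gb$allele; origin_b[row, ] <- gb$origin
    crossovers[[row]] <- list(maternal = ga$crossovers, paternal = gb$crossovers)
  }
  finalize_cohort(config, hap_a, hap_b, origin_a, origin_b,
                  ids, breed, generation, crossovers)
}

#' Simulate windowed read-depth data with planted copy-number variants
#'
#' Tiles every chromosome with fixed-width windows and draws per-sample,
#' per-window read counts as Poisson with mean
#' `mean_depth x copy_number / 2` (copy number 2 = diploid baseline).
#' Planted CNVs assign a per-breed copy number to all windows overlapping
#' their region. Uses the current RNG state.
#'
#' @param cohort A `sim_cohort`.
#' @param cnvs Optional data.frame of planted CNVs: `chrom`, `start`, `end`
#'   (1-based, inclusive), `breed` (metadata breed label), `copies` (absolute
#'   copy number: 0, 1, 2, 3, 4, ...).
#' @param window_bp Window width in bp (default 1000).
#' @param mean_depth Expected diploid read count per window.
#' @return Object of class `depth_matrix`: list with `windows` (chrom, start,
#'   end), `counts` (windows x samples), `truth` (the planted CNV table and
#'   the per-window per-sample copy-number matrix).
#' @export
simulate_depth <- function(cohort, cnvs = NULL, window_bp = 1000,
                           mean_depth = 30) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (window_bp <= 0) stop("window_bp must be positive")
  layout <- cohort$layout
  wins <- do.call(rbind, lapply(seq_len(nrow(layout$chrom)), function(ci) {
    len <- layout$chrom$length[ci]
    start <- seq(1, len, by = window_bp)
    data.frame(chrom = layout$chrom$name[ci], start = as.integer(start),
               end = as.integer(pmin(start + window_bp - 1, len)),
               stringsAsFactors = FALSE)
  }))
  n_w <- nrow(wins)
  samples <- cohort$metadata$sample_id
  cn <- matrix(2, n_w, length(samples), dimnames = list(NULL, samples))
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    for (j in seq_len(nrow(cnvs))) {
      ci <- match(cnvs$chrom[j], layout$chrom$name)
      if (is.na(ci) || cnvs$start[j] < 1 ||
          cnvs$end[j] > layout$chrom$length[ci]) {
        stop("planted CNV region outside the genome layout")
      }
      w <- wins$chrom == cnvs$chrom[j] & wins$start <= cnvs$end[j] &
        wins$end >= cnvs$start[j]
      s <- cohort$metadata$breed == cnvs$breed[j]
      if (any(w) && any(s)) cn[w, s] <- cnvs$copies[j]
    }
  }
  counts <- matrix(stats::rpois(n_w * length(samples), mean_depth * cn / 2),
                   n_w, length(samples), dimnames = list(NULL, samples))
  structure(list(windows = wins, counts = counts,
                 truth = list(cnvs = cnvs, copy_number = cn)),
            class = "depth_matrix")
}

#' Default study-scale simulation configuration
#'
#' Builds the layout, founder panel and cross design used throughout the
#' package's validation runs: five 50-Mb autosomes at 1 cM/Mb; the
#' melanin-synthesis (`B`) locus on chromosome 2 and the feather-deposition
#' (`R`) locus at position 5,300,000 of chromosome 5; neutral founder
#' frequencies drawn per breed from Beta(0.8, 0.8) truncated to
#' `[0.05, 0.95]`, with a fraction `frac_aim` of strongly diverged
#' ancestry-informative markers (breed frequencies 0.02 vs 0.98) so that
#' delta-AF > 0.8 screens have hits; founder/F1/F2 cohort sizes scaled down
#' from the resequencing panel.
#'
#' @param seed Master seed; fixes the layout, the panel and the cohort.
#' @param n_snps_per_chrom SNPs simulated per chromosome.
#' @param n_per_founder,n_f1,n_f2 Cohort sizes.
#' @param frac_aim Fraction of ancestry-informative markers.
#' @param missing_rate Per-genotype missingness.
#' @param n_chrom,chrom_length_bp,recomb_rate Genome dimensions.
#' @return A [cross_config()] ready for [breed_cross()].
#' @export
sim_study_config <- function(seed = 1, n_snps_per_chrom = 1040,
                             n_per_founder = 30, n_f1 = 60, n_f2 = 320,
                             frac_aim = 0.1, missing_rate = 0.02,
                             n_chrom = 5, chrom_length_bp = 5e7,
                             recomb_rate = 1) {
  set.seed(seed)
  chrom <- paste0("chr", seq_len(n_chrom))
  len <- rep(chrom_length_bp, n_chrom)
  snp_pos <- lapply(seq_len(n_chrom), function(i) {
    sort(sample.int(chrom_length_bp, n_snps_per_chrom))
  })
  names(snp_pos) <- chrom
  causal_b <- list(chrom = chrom[min(2, n_chrom)],
                   pos = floor(chrom_length_bp / 2))
  causal_r <- list(chrom = chrom[n_chrom], pos = min(5300000, chrom_length_bp))
  snp_pos[[causal_b$chrom]] <- sort(unique(c(snp_pos[[causal_b$chrom]],
                                             causal_b$pos)))
  snp_pos[[causal_r$chrom]] <- sort(unique(c(snp_pos[[causal_r$chrom]],
                                             causal_r$pos)))
  layout <- genome_layout(chrom, len, snp_pos, recomb_rate)

  m <- layout$n_snps
  rbeta_trunc <- function(n) pmin(pmax(stats::rbeta(n, 0.8, 0.8), 0.05), 0.95)
  freq1 <- rbeta_trunc(m)
  freq2 <- rbeta_trunc(m)
  aim <- stats::runif(m) < frac_aim
  hi <- stats::runif(sum(aim)) < 0.5  # which breed carries the high allele
  freq1[aim] <- ifelse(hi, 0.98, 0.02)
  freq2[aim] <- ifelse(hi, 0.02, 0.98)
  chrom_of <- rep(layout$chrom$name, vapply(layout$snp, length, integer(1)))
  pos_of <- unlist(layout$snp, use.names = FALSE)
  ib <- which(chrom_of == causal_b$chrom & pos_of == causal_b$pos)
  ir <- which(chrom_of == causal_r$chrom & pos_of == causal_r$pos)
  freq1[ib] <- 1; freq2[ib] <- 0  # B fixed in the Liancheng-like breed
  freq1[ir] <- 0; freq2[ir] <- 1  # R fixed in the Pekin-like breed
  fp <- founder_panel(layout, freq1, freq2, causal_b, causal_r)
  cross_config(layout, fp, n_per_founder = n_per_founder, n_f1 = n_f1,
               n_f2 = n_f2, missing_rate = missing_rate,
               seed = sample.int(.Machine$integer.max, 1L))
}

#' Write a simulated cohort to disk (VCF, metadata TSV, truth JSON)
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  contigs <- stats::setNames(cohort$layout$chrom$length,
                             cohort$layout$chrom$name)
  vcf <- file.path(dir, "cohort.vcf")
  write_vcf(cohort$variants, cohort$geno, vcf, contigs = contigs)
  meta <- file.path(dir, "metadata.tsv")
  utils::write.table(cohort$metadata, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- file.path(dir, "truth.json")
  co <- lapply(cohort$truth$crossovers, function(x) {
    if (is.null(x)) NULL else lapply(x, function(df) as.list(df))
  })
  jsonlite::write_json(
    list(causal = cohort$truth$causal,
         diplotypes = cohort$truth$diplotypes,
         crossovers = co),
    truth, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(vcf = vcf, metadata = meta, truth = truth))
}

#' Write a simulated depth matrix as a TSV
#'
#' Columns: `chrom`, `start`, `end`, then one column per sample.
#'
#' @param depth A `depth_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path) {
  stopifnot(inherits(depth, "depth_matrix"))
  utils::write.table(cbind(depth$windows, depth$counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth TSV written by [write_depth()]
#'
#' @param path Input path.
#' @return A `depth_matrix` (without truth).
#' @export
read_depth <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(windows = d[, c("chrom", "start", "end")],
                 counts = as.matrix(d[, -(1:3), drop = FALSE]),
                 truth = NULL),
            class = "depth_matrix")
}
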