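# Shared fixture builders. Everything is generated in code at test time.

# A tiny two-chromosome layout: chr1 carries the beak (B) locus, chr2 the
# feather (R) locus. Useful wherever only the causal diplotypes matter.
tiny_layout <- function(recomb_rate = 1) {
  genome_layout(
    chrom = c("chr1", "chr2"),
    length = c(1e7, 1e7),
    snp_pos = list(chr1 = c(2e6, 5e6, 8e6), chr2 = c(1e6, 5e6, 9e6)),
    recomb_rate = recomb_rate
  )
}

tiny_panel <- function(layout = tiny_layout()) {
  # variants: chr1 2e6/5e6/8e6, chr2 1e6/5e6/9e6; causal at chr1:5e6 (B),
  # chr2:5e6 (R); the rest mildly polymorphic in both breeds
  freq1 <- c(0.5, 1, 0.3, 0.6, 0, 0.4)
  freq2 <- c(0.5, 0, 0.3, 0.6, 1, 0.4)
  founder_panel(layout, freq1, freq2,
                causal_b = list(chrom = "chr1", pos = 5e6),
                causal_r = list(chrom = "chr2", pos = 5e6))
}

tiny_config <- function(seed = 7, n_per_founder = 10, n_f1 = 20, n_f2 = 50,
                        missing_rate = 0, recomb_rate = 1) {
  layout <- tiny_layout(recomb_rate)
  cross_config(layout, tiny_panel(layout), n_per_founder = n_per_founder,
               n_f1 = n_f1, n_f2 = n_f2, missing_rate = missing_rate,
               seed = seed)
}

# Fine-mapping fixture: chr2 carries a 5.1-5.5 Mb candidate region holding
# exactly `n_info` fully fixed ancestry-informative SNPs, one of which is the
# causal feather SNP, so ancestry painting is noise-free. chr1 carries the
# beak locus.
finemap_config <- function(seed, n_f2 = 300, n_info = 36, n_per_founder = 20,
                           n_f1 = 40, recomb_rate = 1) {
  info_pos <- round(seq(5.10e6, 5.50e6, length.out = n_info - 1))
  causal_pos <- 5303994
  chr2_pos <- sort(unique(c(info_pos, causal_pos, c(1e6, 3e6, 8e6))))
  layout <- genome_layout(
    chrom = c("chr1", "chr2"), length = c(2e7, 1e7),
    snp_pos = list(chr1 = c(5e6, 1e7, 1.5e7), chr2 = chr2_pos),
    recomb_rate = recomb_rate
  )
  m <- layout$n_snps
  chrom_of <- rep(layout$chrom$name, lengths(layout$snp))
  pos_of <- unlist(layout$snp, use.names = FALSE)
  freq1 <- rep(0.5, m)
  freq2 <- rep(0.5, m)
  region <- chrom_of == "chr2" & pos_of >= 5.0e6 & pos_of <= 5.6e6
  freq1[region] <- 0  # LC-like breed carries the reference allele...
  freq2[region] <- 1  # ...the PK-like breed the alternate (R side)
  ib <- which(chrom_of == "chr1" & pos_of == 1e7)
  freq1[ib] <- 1; freq2[ib] <- 0
  fp <- founder_panel(layout, freq1, freq2,
                      causal_b = list(chrom = "chr1", pos = 1e7),
                      causal_r = list(chrom = "chr2", pos = causal_pos))
  cross_config(layout, fp, n_per_founder = n_per_founder, n_f1 = n_f1,
               n_f2 = n_f2, missing_rate = 0, seed = seed)
}

# candidate region used with finemap_config cohorts
finemap_region <- function() list(chrom = "chr2", start = 5.1e6, end = 5.5e6)
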