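#' Read a VCF into a variant table and genotype matrix
#'
#' Parses a VCF (v4.x, diploid GT field) via \pkg{vcfR} and returns the
#' per-variant table together with an alternate-allele dosage matrix. Phased
#' (`|`) and unphased (`/`) genotypes are both accepted; `./.` or `.` becomes
#' the missing code `NA`. Multiallelic records are retained but flagged (their
#' dosage counts allele 1 only); records whose REF or ALT spans more than one
#' base are typed `indel`, single-base substitutions `SNP`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return List with `variants` (data.frame: `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `vtype`, `multiallelic`) and `geno` (integer matrix, samples x
#'   variants, entries 0/1/2/`NA`).
#' @seealso [write_vcf()], [apply_filters()]
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  alt1 <- sub(",.*$", "", alt)
  vtype <- ifelse(!multi & nchar(ref) == 1L & nchar(alt1) == 1L, "SNP", "indel")
  vtype[multi] <- ifelse(nchar(ref[multi]) == 1L & nchar(alt1[multi]) == 1L,
                         "SNP", "indel")
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".", NA_character_, fix[, "ID"]),
    ref = ref, alt = alt, vtype = vtype, multiallelic = multi,
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  geno <- gt_to_dosage(gt)
  geno <- t(geno)  # samples x variants
  colnames(geno) <- paste0(variants$chrom, ":", variants$pos)
  ord <- order(variants$chrom, variants$pos)
  list(variants = variants[ord, , drop = FALSE],
       geno = geno[, ord, drop = FALSE])
}

# "0/1", "1|1", "./.", "." -> alternate-allele dosage (allele 1 only)
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt) | a2 == ""] <- NA_integer_
  mode(d) <- "integer"
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a variant table and genotype matrix as a VCF v4.2 file
#'
#' Emits a minimal plain-text VCF (GT-only FORMAT) that round-trips through
#' [read_vcf()]. Dosage 0/1/2 is written as `0/0`, `0/1`, `1/1`; `NA` as
#' `./.`.
#'
#' @param variants Variant table as produced by [read_vcf()] (columns `chrom`,
#'   `pos`, `ref`, `alt`; optional `id`).
#' @param geno Samples x variants dosage matrix with sample rownames.
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, geno, path, contigs = NULL) {
  stopifnot(nrow(variants) == ncol(geno), !is.null(rownames(geno)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=duckmap",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt[!is.na(geno) & geno == 0L] <- "0/0"
  gt[!is.na(geno) & geno == 1L] <- "0/1"
  gt[!is.na(geno) & geno == 2L] <- "1/1"
  id <- if ("id" %in% names(variants)) {
    ifelse(is.na(variants$id), ".", variants$id)
  } else "."
  body <- paste(variants$chrom, variants$pos, id, variants$ref, variants$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Minor allele frequency of one variant
#'
#' Alternate-allele frequency over non-missing alleles, folded to
#' `min(p, 1 - p)`. Returns `NA` when every genotype is missing (such a
#' variant fails the MAF filter).
#'
#' @param g Dosage vector (0/1/2/`NA`) for one variant.
#' @return MAF in `[0, 0.5]`, or `NA`.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) return(NA_real_)
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Apply the study SNP filters to a variant table and genotype matrix
#'
#' Filters, in order: (1) biallelic — drop multiallelic records; (2)
#' missingness — keep variants with missing fraction strictly below
#' `missing_max`; (3) MAF — keep variants with minor allele frequency strictly
#' above `maf_min`. Threshold semantics are the strict inequalities as
#' printed (MAF > 0.05, missing < 0.7): boundary MAF values fail, boundary
#' missingness passes only below the cap. Variant order is preserved and the
#' operation is idempotent.
#'
#' @param variants,geno As returned by [read_vcf()].
#' @param maf_min MAF threshold (default 0.05); variants with `MAF > maf_min`
#'   are kept.
#' @param missing_max Missing-fraction cap (default 0.7); variants with
#'   missing fraction `< missing_max` are kept.
#' @param biallelic_only Drop multiallelic records first (default `TRUE`).
#' @return List with filtered `variants`, `geno`, and `removed`, a named
#'   integer vector of per-rule removal counts in application order.
#' @export
apply_filters <- function(variants, geno, maf_min = 0.05, missing_max = 0.7,
                          biallelic_only = TRUE) {
  stopifnot(nrow(variants) == ncol(geno),
            maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  removed <- c(biallelic = 0L, missing = 0L, maf = 0L)
  keep <- rep(TRUE, nrow(variants))

  if (biallelic_only && nrow(variants) > 0) {
    multi <- if ("multiallelic" %in% names(variants)) {
      variants$multiallelic
    } else {
      grepl(",", variants$alt, fixed = TRUE)
    }
    removed["biallelic"] <- sum(keep & multi)
    keep <- keep & !multi
  }
  if (any(keep)) {
    miss_frac <- colMeans(is.na(geno))
    fail <- keep & !(miss_frac < missing_max)
    removed["missing"] <- sum(fail)
    keep <- keep & !fail
  }
  if (any(keep)) {
    maf <- apply(geno, 2, compute_maf)
    fail <- keep & !(!is.na(maf) & maf > maf_min)
    removed["maf"] <- sum(fail)
    keep <- keep & !fail
  }
  list(variants = variants[keep, , drop = FALSE],
       geno = geno[, keep, drop = FALSE],
       removed = removed)
}
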