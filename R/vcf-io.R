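# VCF ingestion (via vcfR) and a minimal GT-only writer. Diploid GT fields are
# decoded to alternate-allele dosages; half calls and "./." are missing.

#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT fields to alternate-allele dosages in \{0, 1, 2\}.
#' Half-calls (e.g. `./1`) and `./.` are recorded as missing. Multiallelic
#' records (ALT with a comma) are retained but flagged `biallelic = FALSE`
#' so that [filter_variants()] can drop them.
#'
#' @param path VCF 4.x file (plain or bgzipped) with GT fields.
#' @param region optional `"chrom:start-end"` string restricting the sites
#'   returned. An absent chromosome yields an empty matrix with a warning.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      id = as.character(fix[, "ID"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  sites$id[is.na(sites$id)] <- "."
  sites$biallelic <- !grepl(",", sites$alt) & !is.na(sites$alt) &
    nzchar(sites$alt)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT fields: ", path)
  samples <- colnames(gt)
  dosage <- gt_to_dosage(gt)
  gm <- genotype_matrix(sites, dosage, samples)
  if (!is.null(region)) {
    r <- parse_region(region)
    if (!r$chrom %in% gm$sites$chrom) {
      warning("region chromosome '", r$chrom, "' absent from VCF")
      return(subset_gm(gm, sites = integer(0)))
    }
    keep <- gm$sites$chrom == r$chrom & gm$sites$pos >= r$start &
      gm$sites$pos <= r$end
    gm <- subset_gm(gm, sites = keep)
  }
  gm
}

## character GT matrix (e.g. "0/1", "0|1", "./.") -> integer dosage matrix
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d1 <- suppressWarnings(as.integer(a1))
  d2 <- suppressWarnings(as.integer(a2))
  d <- d1 + d2                       # NA propagates from half-calls / ./.
  d[!is.na(d) & (d1 > 1L | d2 > 1L)] <- NA_integer_  # non-primary alt alleles
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as a GT-only VCF
#'
#' Emits a plain-text VCF 4.2 with unphased diploid GT fields; dosages 0, 1,
#' 2 become `0/0`, `0/1`, `1/1` and missing becomes `./.`. Re-reading the
#' file with [read_vcf()] reproduces the dosages exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @export
write_vcf <- function(gm, path) {
  s <- gm$sites
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
  ok <- !is.na(gm$dosage)
  gt[ok] <- gtcode[gm$dosage[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (n_sites(gm) == 0L) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
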