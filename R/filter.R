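# Cohort-level variant filtering: biallelic sites with a minimum minor-allele
# copy count and a minimum minor allele frequency, both computed over called
# alleles pooled across all samples.

#' Filter variants on biallelic state, minor-allele copies and MAF
#'
#' Sites are kept when (in this order of accounting) they are biallelic SNPs,
#' carry at least `min_minor_copies` copies of the minor allele among called
#' alleles, and have a pooled minor allele frequency of at least `maf_min`.
#' Site order is preserved. A per-rule removal report is attached as the
#' `"filter_report"` attribute (also see [filter_report()]).
#'
#' @param gm a [genotype_matrix()].
#' @param min_minor_copies minimum minor-allele copy count (default 4).
#' @param maf_min minimum pooled minor allele frequency (default 0.05).
#' @param biallelic_only drop records flagged multiallelic (default TRUE).
#' @return filtered `genotype_matrix` with a `filter_report` attribute.
#' @export
filter_variants <- function(gm, min_minor_copies = 4L, maf_min = 0.05,
                            biallelic_only = TRUE) {
  if (n_sites(gm) == 0L) stop("empty genotype matrix")
  alt <- rowSums(gm$dosage, na.rm = TRUE)
  ncall <- 2L * rowSums(!is.na(gm$dosage))
  minor <- pmin(alt, ncall - alt)
  maf <- ifelse(ncall > 0L, minor / ncall, 0)

  pass_bi <- if (biallelic_only) gm$sites$biallelic else rep(TRUE, n_sites(gm))
  pass_copies <- minor >= min_minor_copies
  pass_maf <- maf >= maf_min

  report <- data.frame(
    rule = c("input", "multiallelic", "minor_copies", "maf", "retained"),
    n = c(n_sites(gm),
          sum(!pass_bi),
          sum(pass_bi & !pass_copies),
          sum(pass_bi & pass_copies & !pass_maf),
          sum(pass_bi & pass_copies & pass_maf)))
  keep <- pass_bi & pass_copies & pass_maf
  if (!any(keep)) warning("all sites removed by filtering")
  out <- subset_gm(gm, sites = keep)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve (or write) the filter report of a filtered genotype matrix
#'
#' @param gm output of [filter_variants()].
#' @param path optional TSV path; when given the report is also written.
#' @return data.frame with columns `rule` and `n`.
#' @export
filter_report <- function(gm, path = NULL) {
  rep <- attr(gm, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run filter_variants()")
  if (!is.null(path)) write_tsv(rep, path)
  rep
}
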