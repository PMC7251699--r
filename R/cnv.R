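# Coverage-ratio copy-number genotyping for a target region and
# co-segregation tabulation against a SNP genotype.

#' Read a depth profile TSV
#'
#' Four (or five) columns: `chrom`, `start`, `end`, `depth`, optional
#' `sample` (samtools-depth / bedgraph style, but 1-based inclusive as
#' written by [write_depth()]; set `zero_based = TRUE` for bedgraph input).
#'
#' @param path TSV file with a header line.
#' @param zero_based treat `start` as 0-based half-open (bedgraph) and
#'   convert.
#' @return data.frame with `chrom`, `start`, `end`, `depth` (+ `sample`).
#' @export
read_depth <- function(path, zero_based = FALSE) {
  x <- read_tsv(path)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(x)))
  if (zero_based) x$start <- x$start + 1L
  x
}

#' Write a depth profile TSV
#' @param profile data.frame with `chrom`, `start`, `end`, `depth`
#'   (+ optional `sample`).
#' @param path output TSV.
#' @export
write_depth <- function(profile, path) write_tsv(profile, path)

#' Region-versus-background depth ratio
#'
#' Length-weighted mean depth inside the target region, divided by the
#' length-weighted mean depth of the background. The default background is
#' the profiled extent of the region's chromosome minus the region itself
#' (whole-chromosome normalization without self-inflation).
#'
#' @param profile depth profile for one sample: data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive, non-overlapping), `depth`.
#' @param region target region (`"chrom:start-end"` string or list).
#' @param background optional explicit background region; default as
#'   described above.
#' @return list with `region_depth`, `background_depth`, `ratio`.
#' @export
depth_ratio <- function(profile, region, background = NULL) {
  r <- parse_region(region)
  p <- profile[profile$chrom == r$chrom, , drop = FALSE]
  if (!nrow(p)) stop("no depth profiled on chromosome ", r$chrom)
  ov <- pmax(0, pmin(p$end, r$end) - pmax(p$start, r$start) + 1)
  if (sum(ov) == 0) stop("region not covered by the depth profile")
  region_depth <- sum(p$depth * ov) / sum(ov)
  if (is.null(background)) {
    bg_len <- (p$end - p$start + 1) - ov
    bg_sum <- p$depth * ((p$end - p$start + 1) - ov)
  } else {
    b <- parse_region(background)
    pb <- profile[profile$chrom == b$chrom, , drop = FALSE]
    bg_len <- pmax(0, pmin(pb$end, b$end) - pmax(pb$start, b$start) + 1)
    bg_sum <- pb$depth * bg_len
  }
  if (sum(bg_len) == 0 || sum(bg_sum) == 0) stop("uncovered background")
  background_depth <- sum(bg_sum) / sum(bg_len)
  list(region_depth = region_depth, background_depth = background_depth,
       ratio = region_depth / background_depth)
}

#' Call extra tandem copies from a depth ratio
#'
#' A diploid carrying 0/1/2 extra copies of a duplicated segment has
#' expected region/background depth ratios 1.0/1.5/2.0; the default band
#' cut-points 1.25 and 1.75 are the midpoints. Ratios above
#' `max_model_ratio` are called 2 extra copies and flagged as amplification
#' beyond the diploid-duplication model.
#'
#' @param ratio numeric vector of depth ratios (finite, positive).
#' @param cuts band cut-points between 0/1 and 1/2 extra copies.
#' @param max_model_ratio flag threshold (default 2.5).
#' @return data.frame with `ratio`, `extra_copies` (0, 1 or 2), `flagged`.
#' @export
call_copy_number <- function(ratio, cuts = c(1.25, 1.75),
                             max_model_ratio = 2.5) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2])
  if (any(!is.finite(ratio) | ratio <= 0))
    stop("ratios must be finite and positive")
  copies <- ifelse(ratio < cuts[1], 0L, ifelse(ratio < cuts[2], 1L, 2L))
  data.frame(ratio = ratio, extra_copies = copies,
             flagged = ratio > max_model_ratio)
}

#' Genotype a CNV region across a cohort of depth profiles
#'
#' @param profiles data.frame of depth rows for many samples (needs a
#'   `sample` column), or a named list of per-sample profiles.
#' @param region target region (see [parse_region()]).
#' @param background optional explicit background (default: chromosome
#'   minus region).
#' @param ... passed to [call_copy_number()].
#' @return data.frame with `sample`, `region_depth`, `background_depth`,
#'   `ratio`, `extra_copies`, `flagged`.
#' @export
cnv_genotype <- function(profiles, region, background = NULL, ...) {
  if (is.data.frame(profiles)) {
    stopifnot("sample" %in% names(profiles))
    profiles <- split(profiles, profiles$sample)
  }
  rows <- lapply(names(profiles), function(s) {
    dr <- depth_ratio(profiles[[s]], region, background)
    data.frame(sample = s, region_depth = dr$region_depth,
               background_depth = dr$background_depth, ratio = dr$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cn <- call_copy_number(out$ratio, ...)
  out$extra_copies <- cn$extra_copies
  out$flagged <- cn$flagged
  rownames(out) <- NULL
  out
}

#' Co-segregation of a SNP genotype with CNV copy-number calls
#'
#' Tabulates samples over \{hom-ref, het, hom-alt\} x \{0, 1, 2 extra
#' copies\} and reports a descriptive concordance: the fraction of samples
#' in the compatible pairings hom-ref with 0, het with \{0, 1\}, hom-alt
#' with \{1, 2\} extra copies.
#'
#' @param snp_dosage named vector (by sample) of SNP alt-allele dosages
#'   (0/1/2).
#' @param cnv_calls named vector of extra-copy calls, or the output of
#'   [cnv_genotype()].
#' @return list with `table` (3x3 matrix), `concordance`, `n`.
#' @export
cosegregation_table <- function(snp_dosage, cnv_calls) {
  if (is.data.frame(cnv_calls))
    cnv_calls <- stats::setNames(cnv_calls$extra_copies, cnv_calls$sample)
  shared <- intersect(names(snp_dosage), names(cnv_calls))
  if (!length(shared)) stop("no samples shared between SNP and CNV calls")
  g <- snp_dosage[shared]; cn <- cnv_calls[shared]
  tab <- table(factor(g, levels = 0:2,
                      labels = c("hom_ref", "het", "hom_alt")),
               factor(cn, levels = 0:2))
  tab <- matrix(as.integer(tab), 3L, 3L,
                dimnames = list(genotype = c("hom_ref", "het", "hom_alt"),
                                extra_copies = 0:2))
  compatible <- (g == 0 & cn == 0) | (g == 1 & cn %in% 0:1) |
    (g == 2 & cn %in% 1:2)
  list(table = tab, concordance = mean(compatible), n = length(shared))
}
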