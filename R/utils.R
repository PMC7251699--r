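# Internal helpers shared across modules.

#' Parse a "chrom:start-end" region string
#'
#' @param region character scalar of the form `"chr5:47670001-48100000"`, or a
#'   list with elements `chrom`, `start`, `end` (returned unchanged).
#' @return list with `chrom` (character), `start`, `end` (numeric, 1-based
#'   inclusive).
#' @export
parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    return(list(chrom = as.character(region$chrom),
                start = as.numeric(region$start),
                end = as.numeric(region$end)))
  }
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region string (expected chrom:start-end): ", region)
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start < 1 || end < start)
    stop("invalid region coordinates: ", region)
  list(chrom = m[2], start = start, end = end)
}

#' Length of a 1-based inclusive region
#'
#' @param region region string or list (see [parse_region()]).
#' @return numeric length in bp (`end - start + 1`).
#' @export
region_span <- function(region) {
  r <- parse_region(region)
  r$end - r$start + 1
}

## Write a data.frame as a plain TSV (no quoting, no row names).
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## data.frame(chrom,start,end) -> GRanges (1-based inclusive in and out)
df_to_granges <- function(df, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## BED export: 1-based inclusive -> 0-based half-open
#' Write regions as a BED file
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name` and `score` columns.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if (!is.null(df$name)) out$name <- df$name
  if (!is.null(df$score)) {
    if (is.null(out$name)) out$name <- "."
    out$score <- df$score
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file (0-based half-open); only the first three (plus
#'   optional name) columns are used.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when present.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(x[[1]]), start = x[[2]] + 1L,
                    end = x[[3]], stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) out$name <- x[[4]]
  out
}
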