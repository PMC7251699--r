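# Genotype container and population map: the substrate every statistic in the
# package is computed from. Dosages are hard diploid calls (count of alternate
# alleles, 0/1/2) with NA for missing; coordinates are 1-based throughout.

#' Construct a genotype matrix
#'
#' @param sites data.frame with one row per variant site and columns `chrom`,
#'   `pos` (1-based), `id`, `ref`, `alt`, and logical `biallelic`. Multiallelic
#'   records may be carried (with `biallelic = FALSE`, `alt` holding the
#'   comma-separated ALT string); they are removed by [filter_variants()].
#' @param dosage integer matrix, sites x samples, entries in \{0, 1, 2, NA\}.
#' @param samples character vector of sample identifiers (matrix columns).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, samples) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt", "biallelic") %in%
                  names(sites)))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(sites))
    stop("dosage rows (", nrow(dosage), ") != sites (", nrow(sites), ")")
  if (ncol(dosage) != length(samples))
    stop("dosage columns (", ncol(dosage), ") != samples (",
         length(samples), ")")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be hard diploid calls in {0, 1, 2} or NA")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  colnames(dosage) <- samples
  rownames(dosage) <- NULL
  structure(list(sites = sites, dosage = dosage,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "),
      "\n", sep = "")
  cat("  biallelic sites: ", sum(x$sites$biallelic), "\n", sep = "")
  nmiss <- sum(is.na(x$dosage))
  cat("  missing calls: ", nmiss, " (",
      format(100 * nmiss / length(x$dosage), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of sites / samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index and/or sample
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples character, integer or logical index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(samples)) samples <- gm$samples
  if (is.character(samples)) {
    missing <- setdiff(samples, gm$samples)
    if (length(missing))
      stop("unknown samples: ", paste(missing, collapse = ", "))
  }
  d <- gm$dosage[sites, samples, drop = FALSE]
  genotype_matrix(gm$sites[sites, , drop = FALSE], d, colnames(d))
}

#' Read a sample-to-population map
#'
#' Two-column TSV (`sample`, `population`), with or without a header line.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample` and `population`.
#' @export
read_population_map <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- identical(tolower(first[1:2]), c("sample", "population"))
  x <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  x <- x[, 1:2]
  names(x) <- c("sample", "population")
  x$sample <- as.character(x$sample)
  x$population <- as.character(x$population)
  x
}

#' Write a sample-to-population map
#' @param pops data.frame with `sample` and `population` columns.
#' @param path output TSV path.
#' @export
write_population_map <- function(pops, path) {
  write_tsv(pops[, c("sample", "population")], path)
}

## Validate a population map against a genotype matrix and return the
## samples of one population (in matrix order).
pop_samples <- function(gm, pops, population) {
  stopifnot(all(c("sample", "population") %in% names(pops)))
  unknown <- setdiff(pops$sample, gm$samples)
  if (length(unknown))
    stop("population map names samples absent from the genotype matrix: ",
         paste(unknown, collapse = ", "))
  s <- pops$sample[pops$population == population]
  if (!length(s)) stop("no samples mapped to population '", population, "'")
  gm$samples[gm$samples %in% s]
}
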