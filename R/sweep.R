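# Composite selection statistic, genome-wide Bonferroni threshold, merging of
# significant windows into directional sweep regions, closest-gene lookup, and
# the top-level sweep_scan() model object.

#' Z-transformed composite of window F_ST and log2 pi ratio
#'
#' `product = fst_mean * log2(pi_a / pi_b)`, standardized to mean 0 and sd 1
#' across all windows with finite product genome-wide. Positive scores
#' (high F_ST with diversity in A exceeding B) point to a sweep in
#' population B; negative to a sweep in A. Windows with an infinite pi
#' ratio (zero diversity in exactly one population) are excluded from the
#' transform and returned in the `"excluded"` attribute.
#'
#' @param windows table from [window_stats()].
#' @param ratio one of `"log2"` (default) or `"raw"`: whether the product
#'   uses the log2 pi ratio or the raw pi ratio.
#' @return the scored windows with `product`, `z` and `direction` columns;
#'   excluded windows in `attr(, "excluded")`.
#' @export
composite_z <- function(windows, ratio = c("log2", "raw")) {
  ratio <- match.arg(ratio)
  r <- if (ratio == "log2") windows$log2_pi_ratio
       else windows$pi_a / windows$pi_b
  product <- windows$fst_mean * r
  finite <- is.finite(product)
  if (sum(finite) < 2L) stop("need >= 2 windows with finite composite")
  scored <- windows[finite, , drop = FALSE]
  excluded <- windows[!finite, , drop = FALSE]
  p <- product[finite]
  s <- stats::sd(p)
  if (s == 0) stop("degenerate score distribution (sd = 0)")
  scored$product <- p
  scored$z <- (p - mean(p)) / s
  pops <- attr(windows, "populations")
  if (is.null(pops)) pops <- c(a = "pop_a", b = "pop_b")
  scored$direction <- ifelse(scored$z > 0, pops[["b"]], pops[["a"]])
  rownames(scored) <- NULL
  attr(scored, "excluded") <- excluded
  attr(scored, "populations") <- pops
  scored
}

#' Genome-wide Bonferroni Z threshold
#'
#' Standard-normal upper quantile at `alpha / n_windows` (one-sided per
#' tail, applied symmetrically to both tails of the composite score).
#'
#' @param n_windows number of windows tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return the threshold z*.
#' @export
bonferroni_threshold <- function(n_windows, alpha = 0.05) {
  stopifnot(n_windows >= 1)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qnorm(1 - alpha / n_windows)
}

#' Select significant windows and merge them into sweep regions
#'
#' Windows with `|z| > z_star` are selected; per chromosome and direction,
#' windows that overlap or are separated by a gap of less than `max_gap_bp`
#' (strictly: merged when `next$start - prev$end - 1 < max_gap_bp`) are
#' merged. Region boundaries are the min start / max end of member windows;
#' `peak_z` is the largest |z|.
#'
#' @param scores output of [composite_z()].
#' @param z_star significance threshold; when `NULL`, computed by
#'   [bonferroni_threshold()] from the number of scored windows and `alpha`.
#' @param max_gap_bp merge windows closer than this many bp (default 50000).
#' @param alpha used only when `z_star` is `NULL`.
#' @return data.frame of regions: `chrom`, `start`, `end`, `length`,
#'   `direction`, `n_bins`, `peak_z`. The selected (pre-merge) windows are
#'   attached as attribute `"bins"`.
#' @export
select_and_merge <- function(scores, z_star = NULL, max_gap_bp = 50000L,
                             alpha = 0.05) {
  if (is.null(z_star)) z_star <- bonferroni_threshold(nrow(scores), alpha)
  sig <- scores[abs(scores$z) > z_star, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      direction = character(0), n_bins = integer(0),
                      peak_z = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) {
    attr(empty, "bins") <- sig
    attr(empty, "z_star") <- z_star
    return(empty)
  }
  pieces <- lapply(split(sig, sig$direction), function(s) {
    gr <- df_to_granges(s)
    merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap_bp)
    hit <- GenomicRanges::findOverlaps(gr, merged)
    peak <- tapply(abs(s$z)[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit), max)
    nb <- tabulate(S4Vectors::subjectHits(hit), length(merged))
    out <- granges_to_df(merged)
    out$length <- out$end - out$start + 1L
    out$direction <- s$direction[1L]
    out$n_bins <- nb
    out$peak_z <- as.numeric(peak)
    out
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bins") <- sig
  attr(out, "z_star") <- z_star
  out
}

#' Closest genes for sweep regions
#'
#' Genes overlapping a region are reported at distance 0; otherwise the
#' nearest gene by boundary distance, with all tied genes reported.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (e.g. from
#'   [select_and_merge()]).
#' @param genes data.frame with `chrom`, `start`, `end`, `gene` columns, or
#'   a `GRanges` with a `gene` (or `Name`/`ID`) metadata column.
#' @return data.frame with `chrom`, `start`, `end`, `gene`, `distance`.
#' @export
closest_genes <- function(regions, genes) {
  if (!nrow(regions)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0),
                      distance = numeric(0)))
  }
  if (methods::is(genes, "GRanges")) {
    nm <- S4Vectors::mcols(genes)
    gene_names <- if (!is.null(nm$gene)) nm$gene
      else if (!is.null(nm$Name)) nm$Name else nm$ID
    gdf <- granges_to_df(genes)
    gdf$gene <- as.character(gene_names)
    genes <- gdf
  }
  if (!nrow(genes)) {
    warning("empty gene track: no associations")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene = character(0),
                      distance = numeric(0)))
  }
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- genes[genes$chrom == r$chrom, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    d <- ifelse(g$end < r$start, r$start - g$end,
                ifelse(g$start > r$end, g$start - r$end, 0))
    dmin <- min(d)
    hit <- g[d == dmin, , drop = FALSE]
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               gene = hit$gene, distance = dmin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan two populations for selective sweeps
#'
#' The package's central routine: computes per-site Weir-Cockerham F_ST,
#' dAF and per-population pi from diploid genotypes, summarizes them in
#' overlapping windows, Z-transforms the product of window F_ST and the
#' log2 pi ratio, applies a genome-wide Bonferroni threshold, and merges
#' significant windows into directional sweep regions.
#'
#' The sign convention: positive composite scores (diversity retained in
#' `pop_a`, lost in `pop_b`) mark candidate sweeps in `pop_b`; negative
#' scores mark sweeps in `pop_a`.
#'
#' @param gm a [genotype_matrix()] (typically after [filter_variants()]).
#' @param pops population map data.frame.
#' @param pop_a,pop_b the two population labels; the pi ratio is
#'   `pop_a / pop_b`.
#' @param window_bp,step_bp,min_snps window geometry (defaults 20 kb / 10 kb
#'   / more than 10 SNPs).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param merge_gap_bp merge significant windows closer than this (50 kb).
#' @param ratio `"log2"` (default) or `"raw"` composite (see
#'   [composite_z()]).
#' @param chrom_len optional named chromosome lengths.
#' @param genes optional gene track for closest-gene annotation (see
#'   [closest_genes()]).
#' @return object of class `sweep_scan` with elements `sites`, `windows`,
#'   `scores`, `z_star`, `regions`, `bins`, `excluded_windows`,
#'   `populations`, `params`, and (when `genes` given) `region_genes`.
#' @examples
#' cfg <- sim_config(seed = 7, chrom_len_bp = 2e6, n_sites = 4000,
#'                   n_per_pop = 20,
#'                   sweep_specs = data.frame(chrom = "chr1", start = 8e5,
#'                                            end = 1.1e6,
#'                                            target_pop = "pop2",
#'                                            residual_af = 0.02,
#'                                            site_thinning = 0.9))
#' sim <- simulate_cohort(cfg, annotation = FALSE, depth = FALSE)
#' fit <- sweep_scan(sim$gm, sim$pops, "pop1", "pop2",
#'                   chrom_len = c(chr1 = 2e6))
#' fit
#' @export
sweep_scan <- function(gm, pops, pop_a, pop_b,
                       window_bp = 20000L, step_bp = 10000L, min_snps = 11L,
                       alpha = 0.05, merge_gap_bp = 50000L,
                       ratio = c("log2", "raw"), chrom_len = NULL,
                       genes = NULL) {
  ratio <- match.arg(ratio)
  sites <- site_stats(gm, pops, pop_a, pop_b)
  windows <- window_stats(sites, window_bp = window_bp, step_bp = step_bp,
                          min_snps = min_snps, chrom_len = chrom_len)
  scores <- composite_z(windows, ratio = ratio)
  z_star <- bonferroni_threshold(nrow(scores), alpha)
  regions <- select_and_merge(scores, z_star, max_gap_bp = merge_gap_bp)
  fit <- structure(list(
    sites = sites, windows = windows, scores = scores, z_star = z_star,
    regions = regions, bins = attr(regions, "bins"),
    excluded_windows = attr(scores, "excluded"),
    populations = c(a = pop_a, b = pop_b),
    params = list(window_bp = window_bp, step_bp = step_bp,
                  min_snps = min_snps, alpha = alpha,
                  merge_gap_bp = merge_gap_bp, ratio = ratio)),
    class = "sweep_scan")
  if (!is.null(genes)) fit$region_genes <- closest_genes(regions, genes)
  fit
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("sweep_scan: ", x$populations[["a"]], " vs ", x$populations[["b"]],
      "\n", sep = "")
  cat("  windows scored: ", nrow(x$scores), " (", x$params$window_bp / 1000,
      " kb, step ", x$params$step_bp / 1000, " kb, > ",
      x$params$min_snps - 1L, " SNPs)\n", sep = "")
  cat("  Bonferroni |z| threshold: ", format(x$z_star, digits = 4),
      " (alpha = ", x$params$alpha, ")\n", sep = "")
  cat("  significant windows: ", nrow(x$bins), "; merged regions: ",
      nrow(x$regions), "\n", sep = "")
  for (p in x$populations)
    cat("    sweeps in ", p, ": ", sum(x$regions$direction == p), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  reg <- object$regions
  out <- list(
    populations = object$populations,
    n_windows = nrow(object$scores),
    n_excluded = nrow(object$excluded_windows),
    z_star = object$z_star,
    n_significant_bins = nrow(object$bins),
    n_regions = nrow(reg),
    regions_by_direction = table(reg$direction),
    mean_region_kb = if (nrow(reg)) mean(reg$length) / 1000 else NA_real_,
    regions = reg)
  class(out) <- "summary.sweep_scan"
  out
}

#' @export
print.summary.sweep_scan <- function(x, ...) {
  cat("Sweep scan summary (", x$populations[["a"]], " vs ",
      x$populations[["b"]], ")\n", sep = "")
  cat("  windows scored:", x$n_windows,
      "| excluded (infinite pi ratio):", x$n_excluded, "\n")
  cat("  |z| threshold:", format(x$z_star, digits = 4),
      "| significant windows:", x$n_significant_bins, "\n")
  cat("  merged sweep regions:", x$n_regions,
      "(mean", format(x$mean_region_kb, digits = 4), "kb)\n")
  if (x$n_regions) {
    cat("\n")
    print(utils::head(x$regions[order(-x$regions$peak_z), ], 10L))
  }
  invisible(x)
}

#' Manhattan-style plot of the composite score
#'
#' @param x a `sweep_scan` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sweep_scan <- function(x, ...) {
  sc <- x$scores
  chroms <- unique(sc$chrom)
  offset <- stats::setNames(c(0, cumsum(tapply(sc$end, sc$chrom, max)))[
    seq_along(chroms)], chroms)
  pos <- (sc$start + sc$end) / 2 + offset[sc$chrom]
  col <- ifelse(abs(sc$z) > x$z_star, "firebrick",
                c("grey40", "grey65")[match(sc$chrom, chroms) %% 2 + 1])
  graphics::plot(pos / 1e6, sc$z, pch = 16, cex = 0.4, col = col,
                 xlab = "position (Mb)", ylab = "composite Z", ...)
  graphics::abline(h = c(-x$z_star, x$z_star), lty = 2, col = "firebrick")
  invisible(x)
}

#' Export sweep regions
#'
#' @param fit a `sweep_scan` object.
#' @param tsv,bed optional output paths (1-based TSV and 0-based half-open
#'   BED).
#' @return the region table, invisibly.
#' @export
export_regions <- function(fit, tsv = NULL, bed = NULL) {
  reg <- fit$regions
  if (!is.null(tsv)) write_tsv(reg, tsv)
  if (!is.null(bed)) {
    b <- reg
    b$name <- if (nrow(b)) paste0("sweep_", b$direction) else character(0)
    b$score <- round(b$peak_z, 3)
    write_bed(b, bed)
  }
  invisible(reg)
}
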