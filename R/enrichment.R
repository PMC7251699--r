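# dAF-bin functional-category enrichment (M-values + chi-squared) and
# region-set overlap enrichment (one-sided Fisher + BH-FDR over a bin
# universe).

#' dAF-bin functional-category enrichment
#'
#' Bins sites by dAF into 10 bins of width 0.1 (half-open \[lo, hi), last
#' bin closed so dAF = 1 falls in bin 9), then for each (category, bin)
#' computes the M-value: the log2 ratio of the category's relative SNP
#' frequency in the bin to its relative frequency across all bins. Per bin,
#' a goodness-of-fit chi-squared compares observed category counts with
#' expectations from the overall proportions (df = K - 1), with
#' standardized residuals per cell; a secondary per-(category, bin) 2x2
#' chi-squared is also reported. Categories with zero overall count are
#' dropped; empty bins get `NA` M-values.
#'
#' @param delta_af per-site dAF values (numeric vector), or a divergence
#'   table with a `delta_af` column.
#' @param categories per-site category labels (same length/order).
#' @param n_bins number of equal-width bins on \[0, 1\] (default 10).
#' @return object of class `daf_enrichment`: list with `bins` (per-bin
#'   counts and chi-squared results), `m_values` (bins x categories),
#'   `counts`, `residuals`, and `pairwise_p` matrices.
#' @export
delta_af_enrichment <- function(delta_af, categories, n_bins = 10L) {
  if (is.data.frame(delta_af)) delta_af <- delta_af$delta_af
  stopifnot(length(delta_af) == length(categories))
  ok <- !is.na(delta_af) & !is.na(categories)
  delta_af <- delta_af[ok]; categories <- as.character(categories[ok])
  if (any(delta_af < 0 | delta_af > 1)) stop("dAF must lie in [0, 1]")
  width <- 1 / n_bins
  bin <- pmin(floor(delta_af / width), n_bins - 1L)   # dAF = 1 -> last bin
  lev <- 0:(n_bins - 1L)
  cats <- sort(unique(categories))
  counts <- table(factor(bin, levels = lev),
                  factor(categories, levels = cats))
  counts <- matrix(as.integer(counts), nrow = n_bins,
                   dimnames = list(bin = lev, category = cats))
  tot_cat <- colSums(counts)
  keep <- tot_cat > 0L
  counts <- counts[, keep, drop = FALSE]
  cats <- cats[keep]; tot_cat <- tot_cat[keep]
  n_all <- sum(counts)
  n_bin <- rowSums(counts)
  prop_overall <- tot_cat / n_all

  ## M(cat, bin) = log2[(count/n_bin) / (overall proportion)]
  m <- log2(sweep(counts / pmax(n_bin, 1L), 2L, prop_overall, "/"))
  m[n_bin == 0L, ] <- NA_real_
  m[counts == 0L] <- -Inf

  chi <- lapply(seq_len(n_bins), function(i) {
    if (n_bin[i] == 0L || length(cats) < 2L)
      return(list(stat = NA_real_, df = NA_integer_, p = NA_real_,
                  stdres = rep(NA_real_, length(cats))))
    gof <- suppressWarnings(stats::chisq.test(counts[i, ], p = prop_overall))
    list(stat = unname(gof$statistic), df = unname(gof$parameter),
         p = unname(gof$p.value), stdres = unname(gof$stdres))
  })
  residuals <- matrix(unlist(lapply(chi, `[[`, "stdres")),
                      nrow = n_bins, byrow = TRUE,
                      dimnames = dimnames(counts))

  ## secondary per-(category, bin) 2x2 association test
  pairwise <- matrix(NA_real_, n_bins, length(cats),
                     dimnames = dimnames(counts))
  for (j in seq_along(cats)) {
    for (i in seq_len(n_bins)) {
      tab <- matrix(c(counts[i, j], n_bin[i] - counts[i, j],
                      tot_cat[j] - counts[i, j],
                      n_all - n_bin[i] - tot_cat[j] + counts[i, j]), 2L)
      if (any(tab < 0) || n_bin[i] == 0L) next
      pairwise[i, j] <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  bins <- data.frame(bin = lev, lo = lev * width, hi = (lev + 1L) * width,
                     n_snps = as.integer(n_bin),
                     chi2_stat = vapply(chi, `[[`, numeric(1), "stat"),
                     chi2_df = vapply(chi, function(x)
                       as.numeric(x$df), numeric(1)),
                     chi2_p = vapply(chi, `[[`, numeric(1), "p"))
  structure(list(bins = bins, m_values = m, counts = counts,
                 residuals = residuals, pairwise_p = pairwise,
                 n_total = n_all),
            class = "daf_enrichment")
}

#' @export
print.daf_enrichment <- function(x, ...) {
  cat("dAF-bin enrichment: ", x$n_total, " SNPs, ",
      ncol(x$counts), " categories, ", nrow(x$bins), " bins\n", sep = "")
  print(cbind(x$bins, round(x$m_values, 3)))
  invisible(x)
}

#' Heatmap of dAF-bin M-values
#'
#' @param x a `daf_enrichment` object.
#' @param ... ignored.
#' @export
plot.daf_enrichment <- function(x, ...) {
  m <- x$m_values
  m[!is.finite(m)] <- NA
  pal <- grDevices::hcl.colors(51, "Blue-Red 2")
  lim <- max(abs(m), na.rm = TRUE)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "dAF bin", ylab = "")
  graphics::axis(1, at = seq_len(nrow(m)),
                 labels = sprintf("%.1f-%.1f", x$bins$lo, x$bins$hi),
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write the M-value matrix as TSV (bins x categories)
#' @param x a `daf_enrichment` object.
#' @param path output TSV.
#' @export
write_m_values <- function(x, path) {
  df <- data.frame(bin = sprintf("%.1f-%.1f", x$bins$lo, x$bins$hi),
                   n_snps = x$bins$n_snps, x$m_values, check.names = FALSE)
  write_tsv(df, path)
}

#' Region-set overlap enrichment over a bin universe
#'
#' LOLA-style enrichment: for each reference track, universe elements are
#' cross-classified by overlap (at least 1 bp) with the query set and with
#' the reference, giving a 2x2 table `(a, b, c, d)` with
#' `a + b + c + d = |universe|`; a one-sided (enrichment) Fisher's exact
#' test and the odds ratio `(a d)/(b c)` are computed, and p-values are
#' BH-adjusted across the reference collection.
#'
#' @param query `GRanges` or data.frame of candidate regions; every element
#'   must overlap at least one universe element.
#' @param references named list of `GRanges` (or data.frames) reference
#'   tracks.
#' @param universe `GRanges` or data.frame of background elements
#'   (typically the scored 20-kb windows of the sweep scan; see
#'   [windows_to_granges()]).
#' @return data.frame with `reference`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_fisher`, `q_bh`, ordered as given.
#' @export
region_set_enrichment <- function(query, references, universe) {
  as_gr <- function(x) if (methods::is(x, "GRanges")) x else df_to_granges(x)
  query <- as_gr(query); universe <- as_gr(universe)
  if (is.null(names(references)))
    names(references) <- paste0("reference_", seq_along(references))
  orphan <- !IRanges::overlapsAny(query, universe)
  if (any(orphan))
    stop("query elements outside the universe: ",
         paste(utils::head(paste0(GenomicRanges::seqnames(query)[orphan],
                                  ":", GenomicRanges::start(query)[orphan]),
                           5L), collapse = ", "))
  in_query <- IRanges::overlapsAny(universe, query)
  rows <- lapply(names(references), function(nm) {
    in_ref <- IRanges::overlapsAny(universe, as_gr(references[[nm]]))
    a <- sum(in_query & in_ref); b <- sum(in_query & !in_ref)
    cc <- sum(!in_query & in_ref); d <- sum(!in_query & !in_ref)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L),
                            alternative = "greater")$p.value
    or <- if (b * cc == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else (a / b) * (d / cc)
    data.frame(reference = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p_fisher = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_fisher, method = "BH")
  rownames(out) <- NULL
  out
}

#' Convert a window table to GRanges
#'
#' @param windows table from [window_stats()] (or any data.frame with
#'   `chrom`, `start`, `end`).
#' @return `GRanges` (1-based inclusive, as stored).
#' @export
windows_to_granges <- function(windows) df_to_granges(windows)
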