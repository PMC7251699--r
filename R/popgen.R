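# Per-site and windowed population-genetic statistics: allele frequencies,
# dAF, the Weir & Cockerham (1984) two-population F_ST variance components,
# per-site nucleotide diversity, overlapping-window summaries, and per-sample
# heterozygosity / inbreeding F.

#' Per-population reference allele frequencies
#'
#' Computes the reference allele frequency (RAF) from called alleles only,
#' one row per (site, population). Sites with no called genotype in a
#' population get `raf = NA` (frequency undefined).
#'
#' @param gm a [genotype_matrix()].
#' @param pops population map data.frame (`sample`, `population`).
#' @param populations which population labels to tabulate (default: all in
#'   the map).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `population`,
#'   `ref_count`, `n_alleles`, `raf`.
#' @export
allele_frequencies <- function(gm, pops, populations = NULL) {
  if (is.null(populations)) populations <- unique(pops$population)
  out <- lapply(populations, function(p) {
    ss <- pop_samples(gm, pops, p)
    d <- gm$dosage[, ss, drop = FALSE]
    ncall <- 2L * rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    refc <- ncall - alt
    data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
               ref = gm$sites$ref, alt = gm$sites$alt,
               population = p, ref_count = as.integer(refc),
               n_alleles = as.integer(ncall),
               raf = ifelse(ncall > 0L, refc / ncall, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Absolute allele-frequency difference between two populations
#'
#' dAF = |RAF_A - RAF_B|, identical whether computed on reference or
#' alternate frequencies. Sites undefined (no called alleles) in either
#' population, or present in only one table, are skipped; the number skipped
#' is attached as attribute `"n_skipped"`.
#'
#' @param freq_a,freq_b per-population frequency tables as returned by
#'   [allele_frequencies()] (one population each).
#' @return data.frame with `chrom`, `pos`, allele counts for both
#'   populations, `raf_a`, `raf_b` and `delta_af`.
#' @export
delta_af <- function(freq_a, freq_b) {
  key_a <- paste(freq_a$chrom, freq_a$pos)
  key_b <- paste(freq_b$chrom, freq_b$pos)
  i <- match(key_a, key_b)
  shared <- !is.na(i)
  a <- freq_a[shared, , drop = FALSE]
  b <- freq_b[i[shared], , drop = FALSE]
  defined <- !is.na(a$raf) & !is.na(b$raf)
  out <- data.frame(chrom = a$chrom, pos = a$pos,
                    ref = a$ref, alt = a$alt,
                    ref_count_a = a$ref_count, n_a = a$n_alleles,
                    ref_count_b = b$ref_count, n_b = b$n_alleles,
                    raf_a = a$raf, raf_b = b$raf,
                    delta_af = abs(a$raf - b$raf),
                    stringsAsFactors = FALSE)[defined, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!shared) + sum(!defined)
  out
}

#' Weir & Cockerham (1984) two-population F_ST from genotype counts
#'
#' Straight evaluation of the 1984 variance components for a biallelic site
#' and two populations: `a` (among populations), `b` (among individuals
#' within populations), `c` (within individuals), and the estimator
#' `theta = a / (a + b + c)`. Negative estimates are retained; `theta` is
#' `NA` when `a + b + c = 0` (site monomorphic across both populations) or
#' when either population has fewer than 2 called genotypes.
#'
#' @param counts_a,counts_b genotype counts `(hom_ref, het, hom_alt)` for
#'   each population: length-3 vectors or n x 3 matrices (sites in rows).
#' @return data.frame with columns `a`, `b`, `c`, `fst`.
#' @export
site_fst_wc <- function(counts_a, counts_b) {
  ca <- rbind3(counts_a); cb <- rbind3(counts_b)
  n1 <- rowSums(ca); n2 <- rowSums(cb)             # diploid sample sizes
  p1 <- (ca[, 2L] + 2 * ca[, 3L]) / (2 * n1)       # alt allele frequencies
  p2 <- (cb[, 2L] + 2 * cb[, 3L]) / (2 * n2)
  h1 <- ca[, 2L] / n1                              # observed het proportions
  h2 <- cb[, 2L] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  small <- n1 < 2 | n2 < 2
  a[small] <- b[small] <- cc[small] <- fst[small] <- NA_real_
  data.frame(a = a, b = b, c = cc, fst = fst)
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopifnot(ncol(x) == 3L)
  storage.mode(x) <- "double"
  x
}

#' Per-site nucleotide diversity from allele counts
#'
#' The proportion of distinct allele pairs that differ:
#' `pi = 2 * c_ref * c_alt / (n * (n - 1))` with `n = c_ref + c_alt` called
#' alleles. `NA` when `n < 2`.
#'
#' @param ref_count,alt_count called reference/alternate allele counts
#'   (vectorized).
#' @return numeric vector of per-site pi.
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  ifelse(n >= 2, 2 * ref_count * alt_count / (n * (n - 1)), NA_real_)
}

## Genotype count matrices (hom_ref, het, hom_alt) for one population.
genotype_counts <- function(gm, samples) {
  d <- gm$dosage[, samples, drop = FALSE]
  cbind(hom_ref = rowSums(d == 0L, na.rm = TRUE),
        het = rowSums(d == 1L, na.rm = TRUE),
        hom_alt = rowSums(d == 2L, na.rm = TRUE))
}

#' Per-site divergence and diversity table for two populations
#'
#' One row per site: allele counts, RAF and dAF for the two populations,
#' Weir-Cockerham variance components and theta, and per-population site pi.
#' This is the substrate of [window_stats()].
#'
#' @param gm a [genotype_matrix()].
#' @param pops population map.
#' @param pop_a,pop_b population labels (A first: the pi ratio and direction
#'   conventions of the sweep scan are `pop_a / pop_b`).
#' @return data.frame; population labels are kept in the `"populations"`
#'   attribute.
#' @export
site_stats <- function(gm, pops, pop_a, pop_b) {
  sa <- pop_samples(gm, pops, pop_a)
  sb <- pop_samples(gm, pops, pop_b)
  ca <- genotype_counts(gm, sa)
  cb <- genotype_counts(gm, sb)
  wc <- site_fst_wc(ca, cb)
  na <- 2L * as.integer(rowSums(ca))
  nb <- 2L * as.integer(rowSums(cb))
  refa <- 2L * ca[, 1L] + ca[, 2L]
  refb <- 2L * cb[, 1L] + cb[, 2L]
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    ref = gm$sites$ref, alt = gm$sites$alt,
                    ref_count_a = as.integer(refa), n_a = na,
                    ref_count_b = as.integer(refb), n_b = nb,
                    raf_a = ifelse(na > 0L, refa / na, NA_real_),
                    raf_b = ifelse(nb > 0L, refb / nb, NA_real_),
                    stringsAsFactors = FALSE)
  out$delta_af <- abs(out$raf_a - out$raf_b)
  out$a <- wc$a; out$b <- wc$b; out$c <- wc$c; out$fst <- wc$fst
  out$pi_a <- site_pi(refa, na - refa)
  out$pi_b <- site_pi(refb, nb - refb)
  attr(out, "populations") <- c(a = pop_a, b = pop_b)
  out
}

#' Overlapping-window summaries of F_ST and nucleotide diversity
#'
#' Windows start at 1, `step_bp + 1`, `2 * step_bp + 1`, ... on each
#' chromosome and span `window_bp` (1-based inclusive); a site at position p
#' belongs to every window whose span contains p. Per window:
#' `n_snps` = sites with a defined Weir-Cockerham theta, `fst_mean` = the
#' arithmetic mean of those per-site estimates (`fst_ratio`, the
#' ratio-of-summed-components alternative, is also reported), and window pi
#' per population = sum of per-site pi over the full window length, so
#' monomorphic positions contribute zero through the denominator. Windows
#' with `n_snps < min_snps` are dropped. `log2_pi_ratio` =
#' `log2(pi_a / pi_b)`; it is infinite when exactly one population has zero
#' window diversity (such windows are excluded from the composite
#' Z-transform downstream but retained here).
#'
#' @param sites per-site table from [site_stats()] (sorted by chrom, pos).
#' @param window_bp window size in bp (default 20000).
#' @param step_bp step size in bp (default 10000; `window_bp` must be a
#'   multiple).
#' @param min_snps minimum informative SNPs per retained window (default 11,
#'   i.e. strictly more than 10).
#' @param chrom_len optional named vector of chromosome lengths; defaults to
#'   the last site position per chromosome.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `fst_mean`,
#'   `fst_ratio`, `pi_a`, `pi_b`, `log2_pi_ratio`.
#' @export
window_stats <- function(sites, window_bp = 20000L, step_bp = 10000L,
                         min_snps = 11L, chrom_len = NULL) {
  stopifnot(window_bp %% step_bp == 0)
  k <- window_bp %/% step_bp          # windows covering each position
  chroms <- unique(sites$chrom)
  res <- lapply(chroms, function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    len <- if (!is.null(chrom_len) && ch %in% names(chrom_len))
      chrom_len[[ch]] else max(s$pos)
    n_win <- max(1L, ceiling((len - window_bp) / step_bp) + 1L)
    ## window j (1-based) spans [(j-1)*step + 1, (j-1)*step + window_bp];
    ## site at pos p falls in windows j = j_last-k+1 .. j_last with
    ## j_last = floor((p-1)/step) + 1
    j_last <- (s$pos - 1L) %/% step_bp + 1L
    idx <- rep(j_last, each = k) - (k - 1L):0L
    site_of <- rep(seq_len(nrow(s)), each = k)
    ok <- idx >= 1L & idx <= n_win
    idx <- idx[ok]; site_of <- site_of[ok]

    agg <- function(v, f = sum) {
      x <- v[site_of]
      g <- factor(idx, levels = seq_len(n_win))
      as.numeric(tapply(x, g, f, default = 0))
    }
    fst <- s$fst[site_of]
    g <- factor(idx, levels = seq_len(n_win))
    n_def <- as.integer(tapply(!is.na(fst), g, sum, default = 0))
    fst_sum <- as.numeric(tapply(ifelse(is.na(fst), 0, fst), g, sum,
                                 default = 0))
    a_sum <- agg(ifelse(is.na(s$a), 0, s$a))
    abc_sum <- agg(ifelse(is.na(s$a), 0, s$a + s$b + s$c))
    pi_a <- agg(ifelse(is.na(s$pi_a), 0, s$pi_a)) / window_bp
    pi_b <- agg(ifelse(is.na(s$pi_b), 0, s$pi_b)) / window_bp

    start <- (seq_len(n_win) - 1L) * step_bp + 1L
    out <- data.frame(chrom = ch, start = start,
                      end = start + window_bp - 1L,
                      n_snps = n_def,
                      fst_mean = ifelse(n_def > 0L, fst_sum / n_def, NA_real_),
                      fst_ratio = ifelse(abc_sum > 0, a_sum / abc_sum,
                                         NA_real_),
                      pi_a = pi_a, pi_b = pi_b,
                      stringsAsFactors = FALSE)
    out[out$n_snps >= min_snps, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$log2_pi_ratio <- log2(out$pi_a / out$pi_b)
  attr(out, "populations") <- attr(sites, "populations")
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  out
}

#' Per-sample heterozygosity and inbreeding coefficient F
#'
#' For each sample, over its non-missing sites: observed homozygous count
#' `o_hom`; expected homozygous count
#' `e_hom = sum over sites of [1 - 2 p (1 - p) n / (n - 1)]`, with p the
#' pooled cohort reference allele frequency and n the cohort called-allele
#' count at the site (small-sample corrected); inbreeding
#' `F = (o_hom - e_hom) / (n_sites - e_hom)`; and the heterozygous fraction
#' `het = 1 - o_hom / n_sites`.
#'
#' @param gm a [genotype_matrix()] (at least 2 samples).
#' @return data.frame with `sample`, `o_hom`, `e_hom`, `n_sites`, `f_coef`,
#'   `het`.
#' @export
individual_het_F <- function(gm) {
  if (n_samples(gm) < 2L) stop("cohort frequencies need >= 2 samples")
  d <- gm$dosage
  ncall <- 2 * rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  p <- ifelse(ncall > 0, (ncall - alt) / ncall, NA_real_)
  e_site <- ifelse(ncall >= 2,
                   1 - 2 * p * (1 - p) * ncall / (ncall - 1), NA_real_)
  usable <- !is.na(e_site)
  out <- lapply(seq_len(n_samples(gm)), function(j) {
    called <- !is.na(d[, j]) & usable
    o_hom <- sum(d[called, j] != 1L)
    e_hom <- sum(e_site[called])
    n <- sum(called)
    f <- if (abs(n - e_hom) < .Machine$double.eps^0.5) NA_real_
         else (o_hom - e_hom) / (n - e_hom)
    data.frame(sample = gm$samples[j], o_hom = o_hom, e_hom = e_hom,
               n_sites = n, f_coef = f,
               het = if (n > 0) 1 - o_hom / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Concordance of reference allele frequencies between two populations
#'
#' Pearson r-squared over per-site RAF pairs, plus a 2-D histogram of counts
#' on a square grid for plotting.
#'
#' @param freq_a,freq_b per-population frequency tables
#'   ([allele_frequencies()] output, one population each).
#' @param bin_width grid resolution on \[0, 1\] (default 0.05).
#' @return list with `r_squared`, `n` (shared defined sites) and `counts`
#'   (square matrix of bin counts, rows = population A).
#' @export
raf_concordance <- function(freq_a, freq_b, bin_width = 0.05) {
  m <- delta_af(freq_a, freq_b)
  if (nrow(m) < 2L) stop("need >= 2 shared sites with defined frequencies")
  x <- m$raf_a; y <- m$raf_b
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(x, y)^2
  nb <- ceiling(1 / bin_width)
  bin <- function(v) pmin(pmax(floor(v / bin_width) + 1L, 1L), nb)
  counts <- table(factor(bin(x), levels = seq_len(nb)),
                  factor(bin(y), levels = seq_len(nb)))
  list(r_squared = r2, n = nrow(m),
       counts = matrix(as.integer(counts), nrow = nb))
}
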