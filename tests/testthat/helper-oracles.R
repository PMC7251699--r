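# Independent oracles used to validate the package's estimators. Each is a
# deliberately separate route from the implementation it checks: scalar
# transcriptions, brute-force enumerations, and whole-sequence translation.

## Weir & Cockerham (1984) theta via the general per-allele summation form
## (loops over the two alleles and sums components), written independently
## of the closed biallelic form used by site_fst_wc().
oracle_wc_theta <- function(counts_a, counts_b) {
  n <- c(sum(counts_a), sum(counts_b))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  ## per-population frequency and heterozygote proportion for each allele
  freq <- function(cnt, allele) {
    if (allele == "ref") (2 * cnt[1] + cnt[2]) / (2 * sum(cnt))
    else (2 * cnt[3] + cnt[2]) / (2 * sum(cnt))
  }
  hets <- function(cnt) cnt[2] / sum(cnt)   # het involves both alleles
  A <- B <- C <- 0
  for (allele in c("ref", "alt")) {
    p <- c(freq(counts_a, allele), freq(counts_b, allele))
    h <- c(hets(counts_a), hets(counts_b))
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    A <- A + a; B <- B + b; C <- C + hbar / 2
  }
  list(a = A / 2, b = B / 2, c = C / 2,
       theta = if (A + B + C == 0) NA_real_ else A / (A + B + C))
}

## Brute-force windowed pi: enumerate every pair of called allele copies at
## every site, count differing pairs, divide by pairs and window length.
oracle_window_pi <- function(dosages, window_bp) {
  total <- 0
  for (i in seq_len(nrow(dosages))) {
    d <- dosages[i, ]
    d <- d[!is.na(d)]
    alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(alleles)
    if (n < 2) next
    diff <- 0; pairs <- 0
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      pairs <- pairs + 1
      if (alleles[p] != alleles[q]) diff <- diff + 1
    }
    total <- total + diff / pairs
  }
  total / window_bp
}

## One-sided (enrichment) Fisher p by explicit hypergeometric summation
## with binomial coefficients.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c        # reference-positive universe elements
  nq <- a + b       # query elements
  ks <- a:min(nq, K)
  sum(choose(K, ks) * choose(N - K, nq - ks)) / choose(N, nq)
}

## Whole-transcript translation oracle: rebuild the full CDS from the
## (optionally substituted) genome and translate it with Biostrings.
oracle_transcript_proteins <- function(gff, genome, tx_id, chrom, pos, alt) {
  typ <- as.character(gff$type)
  cds <- gff[typ == "CDS"]
  parent <- vapply(as.list(cds$Parent), `[[`, character(1), 1L)
  seg <- cds[parent == tx_id]
  seg <- seg[order(GenomicRanges::start(seg))]
  strand <- as.character(BiocGenerics::strand(seg))[1L]
  ref_chr <- genome[[chrom]]
  alt_chr <- ref_chr
  Biostrings::subseq(alt_chr, pos, pos) <- Biostrings::DNAString(alt)
  build <- function(chr_seq) {
    pieces <- vapply(seq_along(seg), function(k)
      as.character(Biostrings::subseq(chr_seq,
                                      GenomicRanges::start(seg)[k],
                                      GenomicRanges::end(seg)[k])),
      character(1))
    s <- Biostrings::DNAString(paste(pieces, collapse = ""))
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(Biostrings::translate(s, no.init.codon = TRUE))
  }
  list(ref = build(ref_chr), alt = build(alt_chr))
}

## Small handmade genotype matrix builder for unit tests.
make_gm <- function(dosage, chrom = "chr1", pos = NULL, ref = "A",
                    alt = "G") {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = paste0("s", seq_len(m)),
                      ref = rep_len(ref, m), alt = rep_len(alt, m),
                      biallelic = TRUE, stringsAsFactors = FALSE)
  samples <- paste0("smp", seq_len(ncol(dosage)))
  genotype_matrix(sites, dosage, samples)
}

make_pops <- function(n_a, n_b) {
  data.frame(sample = paste0("smp", seq_len(n_a + n_b)),
             population = rep(c("popA", "popB"), c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

## dosage matrix from per-population genotype counts (sites x 1 config)
dosage_from_counts <- function(counts_a, counts_b) {
  c(rep(0L, counts_a[1]), rep(1L, counts_a[2]), rep(2L, counts_a[3]),
    rep(0L, counts_b[1]), rep(1L, counts_b[2]), rep(2L, counts_b[3]))
}
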