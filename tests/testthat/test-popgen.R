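# Allele frequencies, dAF, the Weir-Cockerham estimator, site and windowed
# pi, per-sample heterozygosity/F, and RAF concordance.

test_that("reference allele frequencies count called alleles only", {
  d <- rbind(c(0, 0, 0, 0, 0, NA, 0, 1, 1, 2),
             c(0, 1, 1, 2, NA, NA, NA, NA, NA, NA))
  gm <- make_gm(d)
  pops <- make_pops(5, 5)
  fr <- allele_frequencies(gm, pops)
  a1 <- fr[fr$population == "popA" & fr$pos == 100, ]
  expect_equal(a1$raf, 1.0)                     # all hom-ref
  a2 <- fr[fr$population == "popA" & fr$pos == 200, ]
  expect_equal(a2$raf, 0.5)                     # dosages 0,1,1,2 -> 4/8
  expect_equal(a2$n_alleles, 8L)
  b2 <- fr[fr$population == "popB" & fr$pos == 200, ]
  expect_true(is.na(b2$raf))                    # fully missing -> undefined
  daf <- delta_af(fr[fr$population == "popA", ],
                  fr[fr$population == "popB", ])
  expect_false(200 %in% daf$pos)                # undefined sites excluded
  expect_equal(attr(daf, "n_skipped"), 1L)
})

test_that("dAF is the absolute frequency difference, symmetric in allele", {
  fa <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                   population = "popA", ref_count = c(20, 11, 16),
                   n_alleles = 20L, raf = c(1.0, 0.55, 0.80))
  fb <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                   population = "popB", ref_count = c(0, 11, 11),
                   n_alleles = 20L, raf = c(0.0, 0.55, 0.55))
  daf <- delta_af(fa, fb)
  expect_equal(daf$delta_af, c(1, 0, 0.25))
  ## alternate-frequency computation gives the same dAF
  expect_equal(abs((1 - fa$raf) - (1 - fb$raf)), daf$delta_af)
})

test_that("Weir-Cockerham components match hand values at the boundaries", {
  ## fixed difference, 50 diploids each, no heterozygotes
  fixed <- site_fst_wc(c(50, 0, 0), c(0, 0, 50))
  expect_equal(fixed$fst, 1)
  expect_equal(fixed$a, 0.5)
  expect_equal(fixed$b, 0)
  expect_equal(fixed$c, 0)
  ## identical configurations: theta ~ 0 (may be slightly negative)
  same <- site_fst_wc(c(30, 40, 30), c(30, 40, 30))
  expect_lt(abs(same$fst), 0.02)
  ## monomorphic across both populations: undefined
  mono <- site_fst_wc(c(25, 0, 0), c(25, 0, 0))
  expect_true(is.na(mono$fst))
  ## < 2 called genotypes in a population: skipped
  tiny <- site_fst_wc(c(1, 0, 0), c(10, 5, 5))
  expect_true(is.na(tiny$fst))
})

test_that("theta equals the independent per-allele summation oracle", {
  ## a fixed mixed configuration first
  got <- site_fst_wc(c(30, 20, 0), c(5, 20, 25))
  want <- oracle_wc_theta(c(30, 20, 0), c(5, 20, 25))
  expect_equal(got$fst, want$theta, tolerance = 1e-12)
  expect_equal(got$a, want$a, tolerance = 1e-12)
  expect_equal(got$b, want$b, tolerance = 1e-12)
  expect_equal(got$c, want$c, tolerance = 1e-12)
  ## 1000 random genotype-count configurations
  set.seed(7)
  for (i in 1:1000) {
    ca <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    cb <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    if (sum(ca) < 2 || sum(cb) < 2) next
    got <- site_fst_wc(ca, cb)
    want <- oracle_wc_theta(ca, cb)
    expect_equal(got$fst, want$theta, tolerance = 1e-10)
  }
})

test_that("site pi equals pair enumeration", {
  expect_equal(site_pi(5, 0), 0)                       # monomorphic
  expect_equal(site_pi(2, 2), 4 / 6, tolerance = 1e-12) # 4 of C(4,2) pairs
  expect_equal(site_pi(9, 1), 0.2, tolerance = 1e-12)  # 2*9*1/90
  expect_true(is.na(site_pi(1, 0)))                    # n < 2 undefined
})

test_that("window membership, SNP threshold and means follow the bin rules", {
  ## sites at 20,000 and 20,001 prove the boundary convention
  n_snps_needed <- 12
  pos <- c(seq(500, 9000, length.out = n_snps_needed), 20000, 20001)
  d <- matrix(rep(c(0L, 2L), each = 4), nrow = length(pos),
              ncol = 8, byrow = TRUE)
  d[1, ] <- c(0L, 1L, 0L, 0L, 2L, 1L, 2L, 2L)
  gm <- make_gm(d, pos = as.integer(pos))
  st <- site_stats(gm, make_pops(4, 4), "popA", "popB")
  win <- window_stats(st, min_snps = 1, chrom_len = c(chr1 = 40000))
  ## pos 20000 in windows [1-20000] and [10001-30000]; 20001 in the next two
  in_win <- function(s) win$n_snps[win$start == s]
  expect_equal(in_win(1), n_snps_needed + 1)       # 12 early + site at 20000
  expect_equal(in_win(10001), 2)                   # 20000 and 20001
  expect_equal(in_win(20001), 1)                   # 20001 only
  ## min_snps: 10 dropped, 11 kept
  win10 <- window_stats(st, min_snps = 11, chrom_len = c(chr1 = 40000))
  expect_true(all(win10$n_snps >= 11))
  expect_false(10001 %in% win10$start)
  ## fst_mean is the arithmetic mean of per-site theta
  expect_equal(win$fst_mean[win$start == 1],
               mean(st$fst[st$pos <= 20000], na.rm = TRUE))
})

test_that("windowed pi matches brute-force pairwise counting", {
  set.seed(11)
  m <- 40
  d <- matrix(sample(c(0:2, NA), m * 10, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), m, 10)
  pos <- sort(sample(1:20000, m))
  gm <- make_gm(d, pos = pos)
  st <- site_stats(gm, make_pops(5, 5), "popA", "popB")
  win <- window_stats(st, min_snps = 1, chrom_len = c(chr1 = 20000))
  w1 <- win[win$start == 1, ]
  da <- gm$dosage[, 1:5, drop = FALSE]
  db <- gm$dosage[, 6:10, drop = FALSE]
  expect_equal(w1$pi_a, oracle_window_pi(da, 20000), tolerance = 1e-12)
  expect_equal(w1$pi_b, oracle_window_pi(db, 20000), tolerance = 1e-12)
})

test_that("every interior site with defined theta lands in exactly two windows", {
  set.seed(3)
  cfg <- sim_config(seed = 3, chrom_len_bp = 1e6, n_sites = 800,
                    n_per_pop = 10, sweep_specs = NULL)
  sim <- simulate_neutral(cfg)
  st <- site_stats(sim$gm, sim$pops, "pop1", "pop2")
  interior <- st[st$pos > 10000 & st$pos <= 990000 & !is.na(st$fst), ]
  win <- window_stats(st, min_snps = 1, chrom_len = c(chr1 = 1e6))
  hits <- vapply(seq_len(nrow(interior)), function(i)
    sum(win$start <= interior$pos[i] & win$end >= interior$pos[i]),
    numeric(1))
  expect_true(all(hits == 2))
})

test_that("individual het and F behave at the design points", {
  ## sample 1 homozygous everywhere at polymorphic sites: het 0, F > 0
  d <- cbind(rep(0L, 20),
             matrix(rep(c(0L, 1L, 1L, 2L), 20), nrow = 20, byrow = TRUE))
  hf <- individual_het_F(make_gm(d))
  expect_equal(hf$het[1], 0)
  expect_gt(hf$f_coef[1], 0)
  ## heterozygous everywhere: het 1, F < 0
  expect_equal(hf$het[3], 1)
  expect_lt(hf$f_coef[3], 0)
  ## cohort at p = 0.5, sample het at half its sites: F near 0
  set.seed(5)
  n <- 40
  d2 <- matrix(rbinom(200 * n, 2, 0.5), 200, n)
  hf2 <- individual_het_F(make_gm(d2))
  expect_lt(abs(mean(hf2$f_coef)), 0.05)
})

test_that("RAF concordance is 1 for identical or mirrored frequencies, ~0 for noise", {
  set.seed(9)
  base <- data.frame(chrom = "chr1", pos = 1:500, ref = "A", alt = "G",
                     population = "popA", ref_count = 0L, n_alleles = 100L,
                     raf = runif(500))
  same <- base; same$population <- "popB"
  expect_equal(raf_concordance(base, same)$r_squared, 1)
  mirror <- base; mirror$raf <- 1 - base$raf
  expect_equal(raf_concordance(base, mirror)$r_squared, 1)
  noise <- base; noise$raf <- runif(500)
  expect_lt(raf_concordance(base, noise)$r_squared, 0.05)
  cc <- raf_concordance(base, same)
  expect_equal(dim(cc$counts), c(20L, 20L))
  expect_equal(sum(cc$counts), 500L)
})
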