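# The synthetic-cohort generator: drift model, planted sweeps, annotation
# and depth components, determinism, and file round-trips.

test_that("configs validate drift and sweep geometry", {
  expect_error(sim_config(fst_param = 0), "fst_param")
  expect_error(sim_config(fst_param = 1), "fst_param")
  expect_error(sim_config(chrom_len_bp = 1e6, n_sites = 100,
                          sweep_specs = data.frame(
                            chrom = "chr1", start = 1e5, end = 2e6,
                            target_pop = "pop2")), "bounds")
  expect_error(sim_config(chrom_len_bp = 1e6, n_sites = 100,
                          sweep_specs = data.frame(
                            chrom = "chr1", start = c(1e5, 2e5),
                            end = c(3e5, 4e5), target_pop = "pop2")),
               "overlap")
  expect_error(sim_config(annot_spec = list(enrichment_odds = 0.5)),
               "odds")
  expect_error(sim_config(cnv_spec = list(mean_depth = 0)), "mean_depth")
})

test_that("identical seeds are bit-identical; distinct seeds differ", {
  cfg <- sim_config(seed = 5, chrom_len_bp = 1e6, n_sites = 500,
                    n_per_pop = 10, sweep_specs = NULL)
  s1 <- simulate_neutral(cfg)
  s2 <- simulate_neutral(cfg)
  expect_identical(s1$gm$dosage, s2$gm$dosage)
  expect_identical(s1$gm$sites, s2$gm$sites)
  cfg2 <- sim_config(seed = 6, chrom_len_bp = 1e6, n_sites = 500,
                     n_per_pop = 10, sweep_specs = NULL)
  s3 <- simulate_neutral(cfg2)
  expect_false(identical(s1$gm$dosage, s3$gm$dosage))
})

test_that("the no-drift limit shows no differentiation", {
  cfg <- sim_config(seed = 8, chrom_len_bp = 1e6, n_sites = 2000,
                    n_per_pop = 30, fst_param = 1e-4, sweep_specs = NULL)
  sim <- simulate_neutral(cfg)
  st <- site_stats(sim$gm, sim$pops, "pop1", "pop2")
  expect_lt(mean(st$delta_af, na.rm = TRUE), 0.08)
  expect_lt(abs(mean(st$fst, na.rm = TRUE)), 0.02)
})

test_that("a total sweep removes diversity and fixes divergent boundary sites", {
  cfg <- sim_config(seed = 9, chrom_len_bp = 1e6, n_sites = 2000,
                    n_per_pop = 20, sweep_specs = NULL)
  sim <- simulate_neutral(cfg)
  spec <- list(chrom = "chr1", start = 4e5, end = 6e5, target_pop = "pop2",
               residual_af = 0, site_thinning = 1.0)
  gm2 <- plant_sweep(sim$gm, sim$pops, spec)
  st <- site_stats(gm2, sim$pops, "pop1", "pop2")
  region <- st$pos >= 4e5 & st$pos <= 6e5
  expect_true(all(st$pi_b[region] == 0))
  ## sites where pop2 fixed the allele absent in (fixed) pop1 have dAF = 1
  fx <- fixed_sites(st)
  expect_true(all(fx$pos >= 4e5 & fx$pos <= 6e5))
  ## empty region errors
  expect_error(plant_sweep(sim$gm, sim$pops,
                           list(chrom = "chr7", start = 1, end = 100,
                                target_pop = "pop2", residual_af = 0,
                                site_thinning = 1)), "no sites")
})

test_that("sweep direction matches the scan's sign convention", {
  cfg <- sim_config(seed = 10, chrom_len_bp = 4e6, n_sites = 8000,
                    n_per_pop = 25,
                    sweep_specs = data.frame(
                      chrom = "chr1", start = 1.5e6, end = 1.9e6,
                      target_pop = "pop2", residual_af = 0.02,
                      site_thinning = 0.9))
  sim <- simulate_cohort(cfg, annotation = FALSE, depth = FALSE)
  fit <- sweep_scan(sim$gm, sim$pops, "pop1", "pop2",
                    chrom_len = c(chr1 = 4e6))
  peak <- fit$scores[which.max(abs(fit$scores$z)), ]
  expect_gt(peak$z, 0)                       # pop2 sweep -> positive tail
  expect_equal(peak$direction, "pop2")
  expect_true(peak$start >= 1.4e6 && peak$end <= 2.0e6)
})

test_that("annotation generator round-trips and plants only when asked", {
  cfg <- sim_config(seed = 13, chrom_len_bp = 2e6, n_sites = 500,
                    n_per_pop = 5, sweep_specs = NULL,
                    annot_spec = list(n_genes = 30))
  sim <- simulate_neutral(cfg)
  ann <- simulate_annotation(cfg, sim$gm$sites)
  ## GFF3 file round-trip reproduces the classification
  path <- tempfile(fileext = ".gff3")
  rtracklayer::export(ann$gff, path, format = "gff3")
  tr2 <- derive_tracks(read_gff3(path), sim_chrom_sizes(cfg))
  expect_identical(classify_sites(sim$gm$sites, tr2),
                   ann$baseline_categories)
  ## no CDS length flags in consequence calling (all codon multiples)
  genome <- simulate_genome(sim_chrom_sizes(cfg), sim$gm$sites, seed = 13)
  cons <- call_consequence(sim$gm$sites[1:50, ], ann$gff, genome)
  expect_length(attr(cons, "skipped_transcripts"), 0L)
  ## odds = 1 leaves the positional classification untouched
  expect_identical(ann$categories, ann$baseline_categories)
  ## planting requires dAF
  cfg4 <- sim_config(seed = 13, chrom_len_bp = 2e6, n_sites = 500,
                     n_per_pop = 5, sweep_specs = NULL,
                     annot_spec = list(n_genes = 30, enrichment_odds = 4))
  expect_error(simulate_annotation(cfg4, sim$gm$sites), "delta_af")
})

test_that("depth generator hits the expected ratios for 0 and 2 extra copies", {
  cfg <- sim_config(seed = 15, cnv_spec = list(dup_af = 0.5,
                                               n_samples = 60))
  cnv <- simulate_depth(cfg)
  calls <- cnv_genotype(cnv$profiles, cnv$region)
  merged <- merge(calls, cnv$truth, by = "sample")
  r0 <- merged$ratio[merged$extra_copies.y == 0]
  r2 <- merged$ratio[merged$extra_copies.y == 2]
  expect_true(length(r0) > 0 && length(r2) > 0)
  expect_lt(max(abs(r0 - 1)), 0.15)        # Poisson mean over ~6.2 kb
  expect_lt(max(abs(r2 - 2)), 0.15 * 2)
  ## same seed -> identical profiles
  cnv2 <- simulate_depth(cfg)
  expect_identical(cnv$profiles, cnv2$profiles)
})

test_that("emitted files re-read losslessly and agree with the truth table", {
  cfg <- sim_config(seed = 19, chrom_len_bp = 1e6, n_sites = 800,
                    n_per_pop = 8,
                    sweep_specs = data.frame(chrom = "chr1", start = 4e5,
                                             end = 5e5, target_pop = "pop1",
                                             residual_af = 0,
                                             site_thinning = 1),
                    annot_spec = list(n_genes = 15),
                    cnv_spec = list(n_samples = 10))
  sim <- simulate_cohort(cfg)
  dir <- tempfile()
  paths <- write_cohort(sim, dir, fasta = TRUE)
  gm2 <- read_vcf(paths[["vcf"]])
  expect_identical(unname(gm2$dosage), unname(sim$gm$dosage))
  pops2 <- read_population_map(paths[["popmap"]])
  expect_equal(pops2, sim$pops)
  prof2 <- read_depth(paths[["depth"]])
  expect_equal(prof2$depth, sim$cnv$profiles$depth)
  ## FASTA reference agrees with every VCF REF base
  genome <- Biostrings::readDNAStringSet(paths[["fasta"]])
  names(genome) <- sub("\\s.*$", "", names(genome))
  idx <- sample(n_sites(gm2), 50)
  got <- vapply(idx, function(i) as.character(
    Biostrings::subseq(genome[[gm2$sites$chrom[i]]],
                       gm2$sites$pos[i], gm2$sites$pos[i])), character(1))
  expect_identical(got, gm2$sites$ref[idx])
  ## truth audit: the planted total sweep really is monomorphic in pop1
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  sw <- truth$sweeps
  st <- site_stats(gm2, pops2, "pop1", "pop2")
  inreg <- st$pos >= sw$start & st$pos <= sw$end
  expect_true(all(st$pi_a[inreg] == 0))
  ## and the depth truth matches recomputed calls
  calls <- cnv_genotype(sim$cnv$profiles, sim$cnv$region)
  expect_equal(calls$extra_copies[match(truth$cnv$sample, calls$sample)],
               truth$cnv$extra_copies)
})
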