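# Synthetic two-population cohorts with planted truth: Balding-Nichols drift
# structure, hard-sweep signatures (near-fixation + diversity loss in one
# population), a synthetic gene model with optional planted category
# enrichment among strongly divergent sites, and depth profiles with planted
# tandem duplications.

#' Simulation configuration
#'
#' Defaults describe the package's standard fixture: one 50-Mb chromosome,
#' 100,000 SNPs, 50 diploid samples per population diverged at
#' Balding-Nichols F = 0.1, ten planted sweeps of 200-500 kb (five per
#' population), a 200-gene annotation, and a 6.2-kb tandem duplication
#' genotyped from mean depth 12.
#'
#' @param seed integer seed; every random draw derives from it.
#' @param n_chrom,chrom_len_bp chromosome count and length.
#' @param n_sites total SNP count (split across chromosomes by length).
#' @param n_per_pop diploid samples per population.
#' @param pop_names the two population labels.
#' @param fst_param Balding-Nichols drift parameter F in (0, 1): the
#'   expected Weir-Cockerham differentiation between the populations.
#' @param sweep_specs data.frame with `chrom`, `start`, `end`,
#'   `target_pop`, `residual_af` (residual minor-allele frequency left in
#'   the swept population, default 0.02) and `site_thinning` (fraction of
#'   region sites made fully monomorphic in the swept population, default
#'   0.9); `NULL` for no sweeps. [default_sweep_specs()] builds the
#'   standard ten.
#' @param annot_spec list: `n_genes`, `mean_exons`, `exon_bp`, `intron_bp`,
#'   `utr_bp`, `planted_category`, `enrichment_odds` (odds multiplier for
#'   placing dAF > 0.8 sites into the planted category; 1 = null).
#' @param cnv_spec list: `chrom`, `chrom_len`, `region_start`,
#'   `region_end`, `mean_depth`, `dup_af` (population frequency of the
#'   duplication allele), `n_samples`, `bin_bp` (background aggregation),
#'   `linked_marker` (marker genotype equals the duplication genotype when
#'   TRUE, independent otherwise).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L, chrom_len_bp = 50e6,
                       n_sites = 100000L, n_per_pop = 50L,
                       pop_names = c("pop1", "pop2"),
                       fst_param = 0.1,
                       sweep_specs = default_sweep_specs(chrom_len_bp,
                                                         pop_names),
                       annot_spec = list(),
                       cnv_spec = list()) {
  if (fst_param <= 0 || fst_param >= 1)
    stop("fst_param must lie strictly between 0 and 1")
  annot <- utils::modifyList(
    list(n_genes = 200L, mean_exons = 5L, exon_bp = 150L, intron_bp = 2000L,
         utr_bp = 200L, planted_category = "CDS", enrichment_odds = 1,
         daf_cut = 0.8), annot_spec)
  if (annot$enrichment_odds < 1)
    stop("enrichment_odds must be >= 1 (use 1 for the null)")
  cnv <- utils::modifyList(
    list(chrom = "chr_cnv", chrom_len = 1e6, region_start = 500001L,
         region_end = 506211L, mean_depth = 12, dup_af = 0.5,
         n_samples = 100L, bin_bp = 1000L, linked_marker = TRUE), cnv_spec)
  if (cnv$mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(sweep_specs)) {
    sweep_specs <- as.data.frame(sweep_specs, stringsAsFactors = FALSE)
    if (is.null(sweep_specs$residual_af)) sweep_specs$residual_af <- 0.02
    if (is.null(sweep_specs$site_thinning)) sweep_specs$site_thinning <- 0.9
    if (any(sweep_specs$start < 1 | sweep_specs$end > chrom_len_bp))
      stop("sweep regions must lie within chromosome bounds")
    for (ch in unique(sweep_specs$chrom)) {
      s <- sweep_specs[sweep_specs$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("sweep regions must not overlap")
    }
  }
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_len_bp = chrom_len_bp, n_sites = as.integer(n_sites),
                 n_per_pop = as.integer(n_per_pop), pop_names = pop_names,
                 fst_param = fst_param, sweep_specs = sweep_specs,
                 annot_spec = annot, cnv_spec = cnv),
            class = "sim_config")
}

#' Standard planted-sweep layout
#'
#' Ten non-overlapping sweeps with lengths evenly spaced from 200 to
#' 500 kb, centred in consecutive equal blocks of the first chromosome,
#' alternating target population.
#'
#' @param chrom_len_bp chromosome length.
#' @param pop_names the two population labels.
#' @param n number of sweeps (default 10).
#' @return data.frame usable as `sweep_specs` in [sim_config()].
#' @export
default_sweep_specs <- function(chrom_len_bp, pop_names = c("pop1", "pop2"),
                                n = 10L) {
  len <- round(seq(200e3, 500e3, length.out = n))
  block <- chrom_len_bp / n
  centre <- (seq_len(n) - 0.5) * block
  data.frame(chrom = "chr1",
             start = round(centre - len / 2),
             end = round(centre + len / 2) - 1,
             target_pop = rep(pop_names, length.out = n),
             residual_af = 0.02, site_thinning = 0.9,
             stringsAsFactors = FALSE)
}

#' Chromosome lengths of a configuration
#' @param config a `sim_config`.
#' @return named vector (simulated chromosomes only, CNV chromosome
#'   excluded).
#' @export
sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$chrom_len_bp, config$n_chrom),
                  paste0("chr", seq_len(config$n_chrom)))
}

#' Simulate a neutral two-population cohort (Balding-Nichols)
#'
#' Per site: ancestral alternate-allele frequency p ~ Uniform(0.05, 0.95);
#' each population's frequency ~ Beta(p (1-F)/F, (1-p)(1-F)/F) with
#' F = `fst_param`; diploid genotypes ~ Binomial(2, p_pop) (Hardy-Weinberg
#' within populations). Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `gm` ([genotype_matrix()]) and `pops` (population
#'   map).
#' @export
simulate_neutral <- function(config) {
  set.seed(config$seed)
  sizes <- sim_chrom_sizes(config)
  n_by_chrom <- round(config$n_sites * sizes / sum(sizes))
  sites <- do.call(rbind, lapply(names(sizes), function(ch) {
    data.frame(chrom = ch,
               pos = sort(sample.int(sizes[[ch]], n_by_chrom[[ch]])),
               stringsAsFactors = FALSE)
  }))
  m <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  sites$id <- paste0("snp", seq_len(m))
  sites$ref <- ref; sites$alt <- unname(alt)
  sites$biallelic <- TRUE

  F <- config$fst_param
  p_anc <- stats::runif(m, 0.05, 0.95)
  npp <- config$n_per_pop
  dosage <- matrix(NA_integer_, m, 2L * npp)
  for (k in 1:2) {
    p_pop <- stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    cols <- (k - 1L) * npp + seq_len(npp)
    dosage[, cols] <- stats::rbinom(m * npp, 2L, rep(p_pop, npp))
  }
  samples <- paste0(rep(config$pop_names, each = npp), "_",
                    sprintf("%02d", rep(seq_len(npp), 2L)))
  colnames(dosage) <- samples
  pops <- data.frame(sample = samples,
                     population = rep(config$pop_names, each = npp),
                     stringsAsFactors = FALSE)
  list(gm = genotype_matrix(sites, dosage, samples), pops = pops)
}

#' Plant a hard-sweep signature in one population
#'
#' Within the region, each site's "swept" allele is drawn with probability
#' equal to its current frequency in the target population (a single
#' hitch-hiking haplotype). A `site_thinning` fraction of sites is made
#' fully monomorphic for the swept allele in the target population
#' (removing their diversity contribution); the remainder are redrawn at
#' frequency `1 - residual_af` for the swept allele. The other population
#' is untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param pops population map.
#' @param spec one sweep: list/row with `chrom`, `start`, `end`,
#'   `target_pop`, `residual_af`, `site_thinning`.
#' @return modified `genotype_matrix`.
#' @export
plant_sweep <- function(gm, pops, spec) {
  idx <- which(gm$sites$chrom == spec$chrom & gm$sites$pos >= spec$start &
                 gm$sites$pos <= spec$end)
  if (!length(idx)) stop("sweep region contains no sites: ", spec$chrom,
                         ":", spec$start, "-", spec$end)
  ss <- pop_samples(gm, pops, spec$target_pop)
  cols <- match(ss, gm$samples)
  d <- gm$dosage[idx, cols, drop = FALSE]
  ncall <- 2 * rowSums(!is.na(d))
  p_alt <- ifelse(ncall > 0, rowSums(d, na.rm = TRUE) / ncall, 0.5)
  swept_alt <- stats::rbinom(length(idx), 1L, p_alt)     # 1 = alt allele swept
  thin <- stats::runif(length(idx)) < spec$site_thinning
  eps <- spec$residual_af
  p_new <- ifelse(thin, as.numeric(swept_alt),
                  swept_alt * (1 - eps) + (1 - swept_alt) * eps)
  nspl <- length(cols)
  newd <- matrix(stats::rbinom(length(idx) * nspl, 2L, rep(p_new, nspl)),
                 nrow = length(idx))
  newd[is.na(d)] <- NA_integer_
  gm$dosage[idx, cols] <- newd
  gm
}

#' Simulate a gene model and per-site category assignment
#'
#' Generates a synthetic GFF3 gene model (genes with UTR/CDS exons and
#' introns on both strands, placed independently of the variant data),
#' derives the standard annotation tracks, and classifies the supplied
#' sites. With `enrichment_odds > 1` and dAF supplied, sites with
#' dAF > `daf_cut` are additionally re-assigned to the planted category so
#' that their odds of carrying it are multiplied by the configured factor
#' (emulating a functional class preferentially hit by divergent sites);
#' the planted category's interval track (merged 500-bp neighbourhoods of
#' its assigned sites) is returned for region-set enrichment tests. With
#' `enrichment_odds = 1` the assignment is the purely positional
#' classification: a calibration null.
#'
#' @param config a [sim_config()] (fields in `annot_spec`).
#' @param sites data.frame with `chrom`, `pos`.
#' @param delta_af optional per-site dAF (required when
#'   `enrichment_odds > 1`).
#' @return list with `gff` (`GRanges`), `tracks`, `categories`,
#'   `baseline_categories`, `planted_track`, `planted_category`,
#'   `chrom_sizes`.
#' @export
simulate_annotation <- function(config, sites, delta_af = NULL) {
  set.seed(config$seed + 1L)
  a <- config$annot_spec
  sizes <- sim_chrom_sizes(config)
  gff <- random_gene_model(sizes, a)
  tracks <- derive_tracks(gff, sizes)
  baseline <- classify_sites(sites, tracks)
  categories <- baseline
  if (a$enrichment_odds > 1) {
    if (is.null(delta_af))
      stop("delta_af needed to plant an enrichment (enrichment_odds > 1)")
    b <- mean(baseline == a$planted_category)
    if (b == 0) stop("planted category absent from baseline classification")
    odds <- a$enrichment_odds
    p_star <- odds * b / (1 - b + odds * b)
    q <- (p_star - b) / (1 - b)
    high <- !is.na(delta_af) & delta_af > a$daf_cut &
      categories != a$planted_category
    flip <- high & stats::runif(length(categories)) < q
    categories[flip] <- a$planted_category
  }
  in_cat <- categories == a$planted_category
  planted_track <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sites$chrom[in_cat],
    IRanges::IRanges(pmax(1L, sites$pos[in_cat] - 250L),
                     pmin(sizes[sites$chrom[in_cat]],
                          sites$pos[in_cat] + 250L))))
  list(gff = gff, tracks = tracks, categories = categories,
       baseline_categories = baseline, planted_track = planted_track,
       planted_category = a$planted_category, chrom_sizes = sizes)
}

## Non-overlapping genes with 5'UTR - (CDS exon - intron)* - CDS exon -
## 3'UTR structure, random strand; CDS length forced to a codon multiple.
random_gene_model <- function(sizes, a) {
  recs <- list()
  gi <- 0L
  for (ch in names(sizes)) {
    n_genes <- max(1L, round(a$n_genes * sizes[[ch]] / sum(sizes)))
    n_ex <- pmax(1L, stats::rpois(n_genes, a$mean_exons - 1L) + 1L)
    ex_w <- lapply(n_ex, function(k) {
      w <- pmax(30L, stats::rpois(k, a$exon_bp))
      extra <- sum(w) %% 3L
      if (extra) w[k] <- w[k] + (3L - extra)   # keep CDS a codon multiple
      w
    })
    span <- vapply(seq_len(n_genes), function(i)
      2L * a$utr_bp + sum(ex_w[[i]]) + (n_ex[i] - 1L) * a$intron_bp,
      numeric(1))
    free <- sizes[[ch]] - sum(span) - 2L * n_genes * 1000L
    if (free < 0) stop("annotation does not fit the chromosome")
    u <- sort(stats::runif(n_genes))
    starts <- floor(u * free) + cumsum(c(0, span[-n_genes] + 2000)) + 1001L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    for (i in seq_len(n_genes)) {
      gi <- gi + 1L
      gid <- sprintf("gene%04d", gi); tid <- sprintf("tx%04d", gi)
      s0 <- starts[i]
      utr5 <- c(s0, s0 + a$utr_bp - 1L)
      pos <- utr5[2L] + 1L
      cds <- matrix(NA_integer_, n_ex[i], 2L)
      for (e in seq_len(n_ex[i])) {
        cds[e, ] <- c(pos, pos + ex_w[[i]][e] - 1L)
        pos <- cds[e, 2L] + 1L + a$intron_bp
      }
      utr3 <- c(cds[n_ex[i], 2L] + 1L, cds[n_ex[i], 2L] + a$utr_bp)
      gend <- utr3[2L]
      str <- strands[i]
      ## GFF phase: bases to skip at each segment start to reach a codon
      ## boundary, in transcription order (5'-most segment has phase 0)
      w <- ex_w[[i]]
      consumed <- if (str == "+") c(0L, cumsum(w)[-length(w)])
        else sum(w) - cumsum(w)          # bases read before each segment
      ph <- (3L - consumed %% 3L) %% 3L
      utr_types <- if (str == "+") c("five_prime_UTR", "three_prime_UTR")
        else c("three_prime_UTR", "five_prime_UTR")
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = ch,
        start = c(s0, s0, utr5[1L], cds[, 1L], utr3[1L]),
        end = c(gend, gend, utr5[2L], cds[, 2L], utr3[2L]),
        strand = str,
        type = c("gene", "mRNA", utr_types[1L],
                 rep("CDS", n_ex[i]), utr_types[2L]),
        ID = c(gid, tid, paste0(tid, ".utrA"),
               paste0(tid, ".cds", seq_len(n_ex[i])),
               paste0(tid, ".utrB")),
        parent = c(NA, gid, tid, rep(tid, n_ex[i]), tid),
        name = c(gid, rep(NA, 3L + n_ex[i])),
        phase = c(rep(NA_integer_, 3L), ph, NA_integer_),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Name <- df$name
  gr$Parent <- IRanges::CharacterList(
    lapply(df$parent, function(p) if (is.na(p)) character(0) else p))
  gr$phase <- df$phase
  gr
}

#' Simulate depth profiles with a planted tandem duplication
#'
#' Per sample, per-base read depth is Poisson with mean
#' `mean_depth * (1 + extra_copies / 2)` inside the CNV region and
#' `mean_depth` elsewhere. The region is emitted per-base; the background
#' is emitted in `bin_bp` bins carrying the mean of their per-base draws
#' (distribution-identical for any length-weighted mean over whole bins).
#' Each sample's duplication genotype (0/1/2 extra copies) is drawn
#' binomially at the configured duplication-allele frequency; a linked SNP
#' marker dosage (equal to the duplication genotype, or independent when
#' `linked_marker = FALSE`) is returned for co-segregation analysis.
#'
#' @param config a [sim_config()] (fields in `cnv_spec`).
#' @return list with `profiles` (data.frame incl. `sample`), `truth`
#'   (`sample`, `extra_copies`), `marker` (named dosage vector), `region`
#'   (string).
#' @export
simulate_depth <- function(config) {
  set.seed(config$seed + 2L)
  cv <- config$cnv_spec
  samples <- sprintf("cnv_%03d", seq_len(cv$n_samples))
  extra <- stats::rbinom(cv$n_samples, 2L, cv$dup_af)
  marker <- if (isTRUE(cv$linked_marker)) extra
    else stats::rbinom(cv$n_samples, 2L, cv$dup_af)
  names(marker) <- samples

  ## background bin layout avoiding the region (bins never straddle it)
  edges <- sort(unique(c(seq(1L, cv$chrom_len + 1L, by = cv$bin_bp),
                         cv$region_start, cv$region_end + 1L,
                         cv$chrom_len + 1L)))
  starts <- edges[-length(edges)]; ends <- edges[-1L] - 1L
  in_region <- starts >= cv$region_start & ends <= cv$region_end
  bg_s <- starts[!in_region]; bg_e <- ends[!in_region]
  reg_pos <- cv$region_start:cv$region_end

  profiles <- lapply(seq_along(samples), function(i) {
    lam <- cv$mean_depth
    bg_len <- bg_e - bg_s + 1
    bg_depth <- stats::rpois(length(bg_s), lam * bg_len) / bg_len
    reg_depth <- stats::rpois(length(reg_pos), lam * (1 + extra[i] / 2))
    data.frame(sample = samples[i], chrom = cv$chrom,
               start = c(bg_s, reg_pos), end = c(bg_e, reg_pos),
               depth = c(bg_depth, reg_depth), stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, profiles)
  list(profiles = profiles,
       truth = data.frame(sample = samples, extra_copies = extra,
                          stringsAsFactors = FALSE),
       marker = marker,
       region = sprintf("%s:%d-%d", cv$chrom, cv$region_start,
                        cv$region_end))
}

#' Simulate a full cohort with planted truth
#'
#' Runs [simulate_neutral()], plants every sweep in
#' `config$sweep_specs`, and optionally generates the annotation and depth
#' components. The returned `truth` element records exactly what was
#' planted.
#'
#' @param config a [sim_config()].
#' @param annotation,depth include those components (default TRUE).
#' @return list with `gm`, `pops`, `annotation` (see
#'   [simulate_annotation()]), `cnv` (see [simulate_depth()]), `truth`,
#'   and `config`.
#' @export
simulate_cohort <- function(config, annotation = TRUE, depth = TRUE) {
  sim <- simulate_neutral(config)
  gm <- sim$gm
  if (!is.null(config$sweep_specs)) {
    for (i in seq_len(nrow(config$sweep_specs)))
      gm <- plant_sweep(gm, sim$pops, as.list(config$sweep_specs[i, ]))
  }
  out <- list(gm = gm, pops = sim$pops, config = config)
  daf <- NULL
  if (annotation) {
    fa <- allele_frequencies(gm, sim$pops,
                             populations = config$pop_names[1L])
    fb <- allele_frequencies(gm, sim$pops,
                             populations = config$pop_names[2L])
    daf_tab <- delta_af(fa, fb)
    daf <- rep(NA_real_, n_sites(gm))
    daf[match(paste(daf_tab$chrom, daf_tab$pos),
              paste(gm$sites$chrom, gm$sites$pos))] <- daf_tab$delta_af
    out$annotation <- simulate_annotation(config, gm$sites, daf)
  }
  if (depth) out$cnv <- simulate_depth(config)
  out$truth <- list(
    sweeps = config$sweep_specs,
    fst_param = config$fst_param,
    planted_category = if (annotation)
      out$annotation$planted_category else NULL,
    enrichment_odds = config$annot_spec$enrichment_odds,
    cnv = if (depth) out$cnv$truth else NULL)
  out
}

#' Random reference genome consistent with the variant table
#'
#' Uniform random bases, with every site's position forced to its
#' reference allele.
#'
#' @param chrom_sizes named lengths.
#' @param sites data.frame with `chrom`, `pos`, `ref`.
#' @param seed seed for the base draw.
#' @return `DNAStringSet` named by chromosome.
#' @export
simulate_genome <- function(chrom_sizes, sites, seed = 1L) {
  set.seed(seed)
  seqs <- lapply(names(chrom_sizes), function(ch) {
    s <- sample(c("A", "C", "G", "T"), chrom_sizes[[ch]], replace = TRUE)
    here <- sites$chrom == ch
    s[sites$pos[here]] <- sites$ref[here]
    paste(s, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(chrom_sizes)
  out
}

#' Write a simulated cohort to files
#'
#' Emits VCF, population map TSV, GFF3, depth TSV, a truth JSON, and
#' (optionally) a reference FASTA consistent with the VCF REF column.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created).
#' @param fasta write the reference FASTA (default TRUE; can be skipped
#'   for large chromosomes).
#' @return named vector of the file paths written.
#' @export
write_cohort <- function(sim, dir, fasta = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             popmap = file.path(dir, "populations.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$gm, paths[["vcf"]])
  write_population_map(sim$pops, paths[["popmap"]])
  truth <- sim$truth
  if (!is.null(sim$annotation)) {
    paths[["gff3"]] <- file.path(dir, "annotation.gff3")
    rtracklayer::export(sim$annotation$gff, paths[["gff3"]],
                        format = "gff3")
    paths[["categories"]] <- file.path(dir, "site_categories.tsv")
    write_tsv(data.frame(chrom = sim$gm$sites$chrom,
                         pos = sim$gm$sites$pos,
                         category = sim$annotation$categories),
              paths[["categories"]])
  }
  if (!is.null(sim$cnv)) {
    paths[["depth"]] <- file.path(dir, "depth.tsv")
    write_depth(sim$cnv$profiles, paths[["depth"]])
    truth$cnv_marker <- as.list(sim$cnv$marker)
    truth$cnv_region <- sim$cnv$region
  }
  if (fasta) {
    paths[["fasta"]] <- file.path(dir, "reference.fa")
    genome <- simulate_genome(sim_chrom_sizes(sim$config), sim$gm$sites,
                              seed = sim$config$seed + 3L)
    Biostrings::writeXStringSet(genome, paths[["fasta"]])
  }
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
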