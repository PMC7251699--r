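# Track derivation, site classification, fixed differences, and coding
# consequences.

## A tiny two-gene model written as GFF3: one plus-strand two-exon gene, one
## minus-strand single-exon gene.
tiny_gff <- function() {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t2001\t3500\t.\t+\t.\tID=geneP;Name=GP",
    "chr1\ttest\tmRNA\t2001\t3500\t.\t+\t.\tID=txP;Parent=geneP",
    "chr1\ttest\tfive_prime_UTR\t2001\t2100\t.\t+\t.\tID=txP.u5;Parent=txP",
    "chr1\ttest\tCDS\t2101\t2400\t.\t+\t0\tID=txP.c1;Parent=txP",
    "chr1\ttest\tCDS\t3101\t3400\t.\t+\t0\tID=txP.c2;Parent=txP",
    "chr1\ttest\tthree_prime_UTR\t3401\t3500\t.\t+\t.\tID=txP.u3;Parent=txP",
    "chr1\ttest\tgene\t8001\t9000\t.\t-\t.\tID=geneM;Name=GM",
    "chr1\ttest\tmRNA\t8001\t9000\t.\t-\t.\tID=txM;Parent=geneM",
    "chr1\ttest\tCDS\t8001\t9000\t.\t-\t0\tID=txM.c1;Parent=txM")
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

granges_to_df_test <- function(gr)
  data.frame(start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))

test_that("derived tracks respect strand and the gene-minus-CDS intron rule", {
  gff <- read_gff3(tiny_gff())
  sizes <- c(chr1 = 20000)
  tr <- derive_tracks(gff, sizes)
  ## minus-strand gene: up1kb lies above the gene end
  up <- granges_to_df_test(tr$up1kb)
  expect_true(any(up$start == 9001 & up$end == 10000))  # geneM upstream
  expect_true(any(up$start == 1001 & up$end == 2000))   # geneP upstream
  dn <- granges_to_df_test(tr$down1kb)
  expect_true(any(dn$start == 7001 & dn$end == 8000))   # geneM downstream
  ## intron = gene minus CDS minus UTR: the gap between the CDS exons
  intr <- granges_to_df_test(tr$intron)
  expect_equal(intr$start, 2401)
  expect_equal(intr$end, 3100)                           # geneM fully coding
  ## intergenic complement lengths sum with the gene track to the genome
  glen <- sum(granges_to_df_test(tr$gene)$end -
                granges_to_df_test(tr$gene)$start + 1)
  ilen <- sum(granges_to_df_test(tr$intergenic)$end -
                granges_to_df_test(tr$intergenic)$start + 1)
  expect_equal(glen + ilen, 20000)
})

test_that("classification follows precedence and covers every position", {
  gff <- read_gff3(tiny_gff())
  tr <- derive_tracks(gff, c(chr1 = 20000))
  sites <- data.frame(chrom = "chr1",
                      pos = c(2200, 2050, 1500, 2700, 12000, 9500))
  got <- classify_sites(sites, tr)
  expect_equal(got, c("CDS", "UTR", "up1kb", "intron", "intergenic",
                      "up1kb"))
  ## unknown chromosome
  expect_equal(classify_sites(data.frame(chrom = "chrX", pos = 5), tr),
               "unplaced")
  ## partition: every position maps to exactly one category, deterministically
  all_pos <- data.frame(chrom = "chr1", pos = seq(1, 20000, by = 97))
  cats <- classify_sites(all_pos, tr)
  expect_false(any(is.na(cats)))
  expect_identical(cats, classify_sites(all_pos, tr))
})

test_that("fixed-difference detection is exact at dAF = 1", {
  div <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
                    ref_count_a = c(40L, 40L, 39L, 0L),
                    n_a = c(40L, 40L, 40L, 40L),
                    ref_count_b = c(0L, 1L, 0L, 40L),
                    n_b = c(40L, 98L, 40L, 40L))
  div$raf_a <- div$ref_count_a / div$n_a
  div$raf_b <- div$ref_count_b / div$n_b
  div$delta_af <- abs(div$raf_a - div$raf_b)
  got <- fixed_sites(div)
  expect_equal(got$pos, c(1L, 4L))              # both orientations count
  ## one heterozygote breaks exact fixation; 0.99 below threshold 1
  expect_false(2 %in% got$pos)
  expect_false(3 %in% got$pos)
  ## lower threshold is monotone
  expect_gte(nrow(fixed_sites(div, threshold = 0.9)), nrow(got))
})

test_that("consequence calls match the genetic code on plus-strand codons", {
  ## genome where txP codon 1 is at 2101-2103
  set.seed(8)
  bases <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE)
  bases[2101:2106] <- c("A", "A", "A", "G", "C", "T")  # codons AAA, GCT
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chr1"
  gff <- read_gff3(tiny_gff())
  sites <- data.frame(chrom = "chr1", pos = c(2103L, 2105L),
                      ref = c("A", "C"), alt = c("G", "T"),
                      stringsAsFactors = FALSE)
  got <- call_consequence(sites, gff, genome)
  expect_equal(got$ref_codon, c("AAA", "GCT"))
  expect_equal(got$alt_codon, c("AAG", "GTT"))
  expect_equal(got$consequence, c("synonymous", "missense"))
  expect_equal(got$ref_aa, c("K", "A"))
  expect_equal(got$alt_aa, c("K", "V"))
  ## reference mismatch is an error naming the site
  bad <- data.frame(chrom = "chr1", pos = 2103L, ref = "C", alt = "G")
  expect_error(call_consequence(bad, gff, genome), "2103")
  ## sites outside any CDS yield no rows
  none <- call_consequence(data.frame(chrom = "chr1", pos = 5L, ref = "A",
                                      alt = "G"),
                           gff, genome)
  expect_equal(nrow(none), 0L)
})

test_that("consequences agree with whole-transcript translation on random genes", {
  ## 120 random transcripts x 1 random CDS SNP each, both strands
  cfg <- sim_config(seed = 17, chrom_len_bp = 3e6, n_sites = 10,
                    n_per_pop = 2, sweep_specs = NULL,
                    annot_spec = list(n_genes = 120))
  dummy_sites <- data.frame(chrom = "chr1", pos = c(10L, 20L))
  ann <- simulate_annotation(cfg, dummy_sites)
  gff <- ann$gff
  genome <- simulate_genome(c(chr1 = 3e6),
                            data.frame(chrom = character(0),
                                       pos = integer(0),
                                       ref = character(0)), seed = 17)
  cds <- gff[as.character(gff$type) == "CDS"]
  parent <- vapply(as.list(cds$Parent), `[[`, character(1), 1L)
  set.seed(99)
  checked <- 0L
  for (tx in unique(parent)) {
    seg <- cds[parent == tx][1]
    pos <- sample(GenomicRanges::start(seg):GenomicRanges::end(seg), 1)
    ref <- as.character(Biostrings::subseq(genome[["chr1"]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    site <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    got <- call_consequence(site, gff, genome)
    got <- got[got$transcript == tx, ]
    expect_equal(nrow(got), 1L)
    prot <- oracle_transcript_proteins(gff, genome, tx, "chr1", pos, alt)
    expect_equal(substr(prot$ref, got$codon_index, got$codon_index),
                 got$ref_aa)
    expect_equal(substr(prot$alt, got$codon_index, got$codon_index),
                 got$alt_aa)
    ## no other residue changed
    other <- seq_len(nchar(prot$ref))[-got$codon_index]
    expect_identical(strsplit(prot$ref, "")[[1]][other],
                     strsplit(prot$alt, "")[[1]][other])
    oracle_class <- if (prot$ref == prot$alt) "synonymous"
      else if (got$alt_aa == "*") "stop_gained"
      else if (got$ref_aa == "*") "stop_lost"
      else "missense"
    expect_equal(got$consequence, oracle_class)
    checked <- checked + 1L
  }
  expect_gte(checked, 100L)
})
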