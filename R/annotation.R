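# Functional annotation: derive category tracks from a GFF3 gene model,
# classify sites by precedence, detect fixed differences, and call coding
# consequences of SNPs with the standard genetic code.

#' Read a GFF3 gene model
#'
#' Thin wrapper over `rtracklayer::import` returning a `GRanges` with
#' `type`, `ID`, `Parent`, `Name` and `phase` metadata.
#'
#' @param path GFF3 file.
#' @return `GRanges`.
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Derive functional annotation tracks from a gene model
#'
#' Builds the category tracks used for SNP classification and enrichment:
#' `gene` (full gene spans), `CDS`, `UTR`, `intron` (gene minus CDS, with
#' UTR additionally subtracted when UTR records exist -- note this "gene
#' minus CDS" definition differs from exon-based intron definitions),
#' `up1kb` (1 kb strand-aware upstream of the TSS), `down1kb` (1 kb
#' strand-aware downstream of the TES) and `intergenic` (complement of the
#' gene track). Intervals are clipped to chromosome bounds.
#'
#' @param gff `GRanges` from [read_gff3()] (needs `gene` and `CDS` records;
#'   `five_prime_UTR`/`three_prime_UTR`/`UTR` used when present).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return named list of `GRanges` tracks, with the gene-level `GRanges`
#'   (gene names kept) in attribute `"genes"` and `chrom_sizes` in
#'   attribute `"chrom_sizes"`.
#' @export
derive_tracks <- function(gff, chrom_sizes) {
  stopifnot(!is.null(names(chrom_sizes)))
  set_bounds <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
    GenomicRanges::trim(gr)
  }
  typ <- as.character(gff$type)
  genes <- set_bounds(gff[typ == "gene"])
  nm <- S4Vectors::mcols(genes)
  gene_names <- if (!is.null(nm$Name) && !all(is.na(nm$Name))) nm$Name
    else nm$ID
  S4Vectors::mcols(genes) <- NULL
  genes$gene <- as.character(gene_names)
  cds <- set_bounds(gff[typ == "CDS"])
  utr <- set_bounds(gff[typ %in% c("five_prime_UTR", "three_prime_UTR",
                                   "UTR")])
  gene_u <- GenomicRanges::reduce(unstrand(genes))
  cds_u <- GenomicRanges::reduce(unstrand(cds))
  utr_u <- GenomicRanges::reduce(unstrand(utr))
  exonic <- GenomicRanges::reduce(c(cds_u, utr_u))
  intron <- GenomicRanges::setdiff(gene_u, exonic)
  up1kb <- set_bounds(GenomicRanges::promoters(genes, upstream = 1000L,
                                               downstream = 0L))
  down1kb <- set_bounds(GenomicRanges::flank(genes, width = 1000L,
                                             start = FALSE))
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1L, as.integer(chrom_sizes)))
  intergenic <- GenomicRanges::setdiff(genome, gene_u)
  tracks <- list(gene = gene_u, CDS = cds_u, UTR = utr_u, intron = intron,
                 up1kb = GenomicRanges::reduce(unstrand(up1kb)),
                 down1kb = GenomicRanges::reduce(unstrand(down1kb)),
                 intergenic = intergenic)
  attr(tracks, "genes") <- genes
  attr(tracks, "chrom_sizes") <- chrom_sizes
  tracks
}

unstrand <- function(gr) {
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Classify sites into functional categories by precedence
#'
#' Each site gets the first category in `precedence` whose track contains
#' its position; sites matching no track fall back to the last category in
#' `precedence` when that track is a complement (the default `intergenic`),
#' and sites on chromosomes unknown to the tracks are labelled
#' `"unplaced"`. With the default precedence every placed position maps to
#' exactly one category.
#'
#' @param sites data.frame with `chrom` and `pos`.
#' @param tracks named list of `GRanges` (e.g. [derive_tracks()] output,
#'   possibly extended with user tracks).
#' @param precedence ordered category names; defaults to
#'   `CDS > UTR > up1kb > down1kb > intron > gene > intergenic`, restricted
#'   to the names present in `tracks`.
#' @return character vector of categories, one per site.
#' @export
classify_sites <- function(sites, tracks,
                           precedence = c("CDS", "UTR", "up1kb", "down1kb",
                                          "intron", "gene", "intergenic")) {
  precedence <- precedence[precedence %in% names(tracks)]
  if (!length(precedence)) stop("precedence matches no track names")
  pos <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  out <- rep(NA_character_, nrow(sites))
  known <- unique(unlist(lapply(tracks, function(t)
    as.character(GenomeInfoDb::seqlevels(t)))))
  cs <- attr(tracks, "chrom_sizes")
  if (!is.null(cs)) known <- union(known, names(cs))
  unplaced <- !(sites$chrom %in% known)
  out[unplaced] <- "unplaced"
  for (cat in precedence) {
    open <- is.na(out)
    if (!any(open)) break
    hit <- IRanges::overlapsAny(pos[open], tracks[[cat]])
    out[open][hit] <- cat
  }
  out[is.na(out)] <- utils::tail(precedence, 1L)
  out
}

#' Sites fixed for different alleles between two populations
#'
#' Selects sites with `dAF >= threshold`. At the default threshold of 1 the
#' test is exact on integer allele counts (one population fixed for the
#' reference allele and the other fixed for the alternate among called
#' alleles), avoiding floating-point boundary artifacts.
#'
#' @param divergence table with allele counts per population
#'   ([site_stats()] or [delta_af()] output).
#' @param threshold minimum dAF (default 1.0).
#' @return the subset of rows passing the threshold.
#' @export
fixed_sites <- function(divergence, threshold = 1.0) {
  d <- divergence
  ok <- d$n_a > 0L & d$n_b > 0L
  num <- abs(as.double(d$ref_count_a) * d$n_b -
               as.double(d$ref_count_b) * d$n_a)
  den <- as.double(d$n_a) * d$n_b
  keep <- if (threshold == 1) ok & num == den else ok & num >= threshold * den
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call coding consequences of SNPs
#'
#' For each SNP falling in the CDS of a well-formed transcript, locates the
#' codon via strand-aware CDS concatenation (honouring the phase of the
#' 5'-most CDS segment), substitutes the alternate base
#' (reverse-complemented on minus-strand transcripts), translates with the
#' standard genetic code, and classifies the change as `synonymous`,
#' `missense`, `stop_gained` or `stop_lost`. Transcripts whose CDS length
#' is not a multiple of 3 are skipped and listed in the
#' `"skipped_transcripts"` attribute. Sites outside any CDS yield no rows.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (single
#'   bases).
#' @param gff gene model `GRanges` ([read_gff3()]).
#' @param genome `DNAStringSet` named by chromosome (the reference the
#'   sites were called against); a mismatch between a site's `ref` and the
#'   sequence is an error.
#' @return data.frame with one row per (site, overlapping transcript):
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `transcript`, `codon_index`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `consequence`.
#' @export
call_consequence <- function(sites, gff, genome) {
  typ <- as.character(gff$type)
  cds <- gff[typ == "CDS"]
  if (!length(cds)) {
    out <- empty_consequence()
    attr(out, "skipped_transcripts") <- character(0)
    return(out)
  }
  parent <- vapply(as.list(cds$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  tx_gene <- transcript_gene_map(gff)

  rows <- list(); skipped <- character(0)
  for (tx in unique(parent)) {
    seg <- cds[parent == tx]
    seg <- seg[order(GenomicRanges::start(seg))]
    strand <- as.character(BiocGenerics::strand(seg))[1L]
    chrom <- as.character(GenomicRanges::seqnames(seg))[1L]
    widths <- GenomicRanges::width(seg)
    ## phase of the 5'-most segment: bases to discard before the first codon
    ph <- seg$phase
    ph <- if (is.null(ph)) 0L else {
      p0 <- if (strand == "-") ph[length(ph)] else ph[1L]
      if (is.na(p0)) 0L else as.integer(p0)
    }
    if ((sum(widths) - ph) %% 3L != 0L) {
      skipped <- c(skipped, tx)
      next
    }
    hit <- which(sites$chrom == chrom &
                   sites$pos >= min(GenomicRanges::start(seg)) &
                   sites$pos <= max(GenomicRanges::end(seg)))
    if (!length(hit)) next
    cds_seq <- extract_cds_seq(seg, strand, genome, chrom)
    if (ph > 0L) cds_seq <- substring(cds_seq, ph + 1L)

    for (i in hit) {
      pos <- sites$pos[i]
      segi <- which(GenomicRanges::start(seg) <= pos &
                      GenomicRanges::end(seg) >= pos)
      if (!length(segi)) next
      ref_base <- substring(as.character(
        Biostrings::subseq(genome[[chrom]], pos, pos)), 1L, 1L)
      if (!identical(ref_base, sites$ref[i]))
        stop("reference mismatch at ", chrom, ":", pos, " (VCF ref ",
             sites$ref[i], ", FASTA ", ref_base, ")")
      cds_pos <- if (strand == "-") {
        sum(widths[seq_along(widths) > segi]) +
          (GenomicRanges::end(seg)[segi] - pos + 1L)
      } else {
        sum(widths[seq_along(widths) < segi]) +
          (pos - GenomicRanges::start(seg)[segi] + 1L)
      }
      cds_pos <- cds_pos - ph
      if (cds_pos < 1L) next            # inside the phase-trimmed stub
      ci <- (cds_pos - 1L) %/% 3L + 1L
      off <- (cds_pos - 1L) %% 3L + 1L
      ref_codon <- substring(cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)
      sub_base <- if (strand == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sites$alt[i]))) else sites$alt[i]
      alt_codon <- ref_codon
      substring(alt_codon, off, off) <- sub_base
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      klass <- if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "*") "stop_gained"
        else if (ref_aa == "*") "stop_lost"
        else "missense"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = sites$ref[i], alt = sites$alt[i],
        gene = if (tx %in% names(tx_gene)) tx_gene[[tx]] else tx,
        transcript = tx, codon_index = ci,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa, consequence = klass,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_consequence()
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$pos, out$transcript), , drop = FALSE]
  attr(out, "skipped_transcripts") <- skipped
  out
}

empty_consequence <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0),
             transcript = character(0), codon_index = integer(0),
             ref_codon = character(0), alt_codon = character(0),
             ref_aa = character(0), alt_aa = character(0),
             consequence = character(0), stringsAsFactors = FALSE)
}

## transcript id -> gene name (named character vector), via mRNA Parent
## attributes; callers fall back to the transcript id for unknown ids.
transcript_gene_map <- function(gff) {
  typ <- as.character(gff$type)
  tx <- gff[typ %in% c("mRNA", "transcript")]
  ids <- as.character(tx$ID)
  parents <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  genes <- gff[typ == "gene"]
  gname <- as.character(if (!is.null(genes$Name) &&
                              !all(is.na(genes$Name))) genes$Name
                        else genes$ID)
  names(gname) <- as.character(genes$ID)
  out <- ifelse(!is.na(parents) & parents %in% names(gname),
                gname[parents], ids)
  stats::setNames(unname(out), ids)
}

## strand-aware CDS concatenation as a character string
extract_cds_seq <- function(seg, strand, genome, chrom) {
  pieces <- vapply(seq_along(seg), function(k)
    as.character(Biostrings::subseq(genome[[chrom]],
                                    GenomicRanges::start(seg)[k],
                                    GenomicRanges::end(seg)[k])),
    character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
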