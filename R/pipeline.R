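# End-to-end orchestration: filter -> per-site statistics -> sweep scan ->
# enrichment -> fixed sites / consequences -> CNV genotyping, with TSV/BED
# outputs and a JSON run manifest. Deterministic given inputs and
# parameters.

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Values that parse as numbers become numeric.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full scan pipeline
#'
#' Stages (each skipped when its inputs are absent): variant filtering;
#' per-site divergence and diversity; windowed statistics and the
#' composite-Z sweep scan with merged regions and closest genes; dAF-bin
#' M-value enrichment and region-set enrichment against the derived
#' annotation tracks (plus any extra BED tracks); fixed-difference
#' detection and coding-consequence calls (needs GFF3 + FASTA); CNV
#' genotyping and co-segregation with a marker SNP (needs depth input).
#' All outputs are written to `out_dir` together with a JSON manifest
#' recording package version, parameters and input checksums. Given the
#' same inputs and parameters the TSV outputs are byte-identical across
#' reruns.
#'
#' @param config named list (or path to a key=value file, see
#'   [read_pipeline_config()]). Recognized keys: `vcf`, `popmap`, `pop_a`,
#'   `pop_b`, `out_dir` (required); `gff3`, `fasta`, `tracks_bed`
#'   (comma-separated extra BED tracks), `depth`, `marker`
#'   (`chrom:pos` SNP for co-segregation), `region` (restrict the VCF);
#'   numeric `window_bp`, `step_bp`, `min_snps`, `alpha`, `merge_gap_bp`,
#'   `min_minor_copies`, `maf_min`, `cnv_cut_low`, `cnv_cut_high`; string
#'   `ratio` ("log2"/"raw").
#' @return (invisibly) a list with the fitted `sweep_scan` object and the
#'   paths written.
#' @export
run_scan <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  need <- c("vcf", "popmap", "pop_a", "pop_b", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config missing required entries: ",
         paste(missing, collapse = ", "))
  for (f in intersect(c("vcf", "popmap", "gff3", "fasta", "depth"),
                      names(config)))
    if (!file.exists(config[[f]]))
      stop("input file for '", f, "' not found: ", config[[f]])
  p <- function(key, default) if (is.null(config[[key]])) default
    else config[[key]]
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    paths[[name]] <<- path
  }

  gm <- read_vcf(config$vcf, region = config$region)
  pops <- read_population_map(config$popmap)
  gm <- filter_variants(gm, min_minor_copies = p("min_minor_copies", 4L),
                        maf_min = p("maf_min", 0.05))
  emit(filter_report(gm), "filter_report.tsv")

  gff <- if (!is.null(config$gff3)) read_gff3(config$gff3) else NULL
  chrom_len <- NULL
  genes <- NULL
  tracks <- NULL
  if (!is.null(gff)) {
    chrom_len <- stats::setNames(
      as.numeric(tapply(gm$sites$pos, gm$sites$chrom, max)),
      sort(unique(gm$sites$chrom)))
    tracks <- derive_tracks(gff, chrom_len)
    genes <- attr(tracks, "genes")
  }

  fit <- sweep_scan(gm, pops, config$pop_a, config$pop_b,
                    window_bp = p("window_bp", 20000L),
                    step_bp = p("step_bp", 10000L),
                    min_snps = p("min_snps", 11L),
                    alpha = p("alpha", 0.05),
                    merge_gap_bp = p("merge_gap_bp", 50000L),
                    ratio = p("ratio", "log2"),
                    chrom_len = chrom_len, genes = genes)
  emit(fit$windows, "windows.tsv")
  emit(fit$bins, "significant_bins.tsv")
  emit(fit$regions, "sweep_regions.tsv")
  paths[["sweep_regions.bed"]] <- file.path(out_dir, "sweep_regions.bed")
  export_regions(fit, bed = paths[["sweep_regions.bed"]])
  if (!is.null(fit$region_genes)) emit(fit$region_genes,
                                       "closest_genes.tsv")
  emit(fit$sites, "site_divergence.tsv")

  if (!is.null(tracks)) {
    categories <- classify_sites(fit$sites, tracks)
    enr <- delta_af_enrichment(fit$sites$delta_af, categories)
    emit(enr$bins, "delta_af_bins.tsv")
    paths[["delta_af_mvalues.tsv"]] <- file.path(out_dir,
                                                 "delta_af_mvalues.tsv")
    write_m_values(enr, paths[["delta_af_mvalues.tsv"]])
    refs <- tracks[setdiff(names(tracks), "intergenic")]
    if (!is.null(config$tracks_bed)) {
      for (bp in strsplit(config$tracks_bed, ",")[[1]]) {
        bp <- trimws(bp)
        refs[[tools::file_path_sans_ext(basename(bp))]] <-
          df_to_granges(read_bed(bp))
      }
    }
    universe <- windows_to_granges(fit$scores)
    if (nrow(fit$regions)) {
      rse <- region_set_enrichment(df_to_granges(fit$regions), refs,
                                   universe)
      emit(rse, "region_enrichment.tsv")
    }
    fixed <- fixed_sites(fit$sites)
    emit(fixed, "fixed_sites.tsv")
    if (!is.null(config$fasta) && nrow(fixed)) {
      genome <- Biostrings::readDNAStringSet(config$fasta)
      names(genome) <- sub("\\s.*$", "", names(genome))
      cons <- call_consequence(fixed, gff, genome)
      emit(cons, "consequences.tsv")
    }
  }

  if (!is.null(config$depth)) {
    profiles <- read_depth(config$depth)
    region <- config$cnv_region
    if (is.null(region)) stop("depth given but no cnv_region configured")
    calls <- cnv_genotype(profiles, region,
                          cuts = c(p("cnv_cut_low", 1.25),
                                   p("cnv_cut_high", 1.75)))
    emit(calls, "cnv_calls.tsv")
    if (!is.null(config$marker)) {
      mk <- strsplit(config$marker, ":")[[1]]
      idx <- which(gm$sites$chrom == mk[1] &
                     gm$sites$pos == as.numeric(mk[2]))
      if (length(idx) == 1L) {
        snp <- gm$dosage[idx, ]
        cs <- cosegregation_table(snp, calls)
        tab <- data.frame(genotype = rownames(cs$table), cs$table,
                          check.names = FALSE)
        emit(tab, "cosegregation.tsv")
      }
    }
  }

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = lapply(
      config[intersect(c("vcf", "popmap", "gff3", "fasta", "depth"),
                       names(config))],
      function(f) unname(tools::md5sum(f))),
    n_sites_retained = n_sites(gm),
    n_windows = nrow(fit$scores),
    z_star = fit$z_star,
    n_regions = nrow(fit$regions),
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, paths = paths,
                 manifest = file.path(out_dir, "manifest.json")))
}
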