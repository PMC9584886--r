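#' End-to-end pipelines
#'
#' Wires the modules into the three standard skim-seq analyses:
#' `aneuploidy` (bins -> copy ratios -> dosage calls), `introgression`
#' (bins -> copy ratios -> segmentation -> translocation calls ->
#' segregation summary) and `genotyping` (parental pileups -> SNP discovery
#' -> progeny calls -> haplotype blocks). A pipeline takes a configuration
#' list (or YAML path), writes its TSV outputs and optional plots under
#' `out_dir`, and returns a manifest of outputs with MD5 checksums.
#'
#' @name pipeline
NULL

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

cfg_get <- function(config, key, default = NULL, required = FALSE) {
  v <- config[[key]]
  if (is.null(v)) {
    if (required) stop("pipeline config is missing required key: ", key)
    v <- default
  }
  v
}

manifest_entry <- function(paths) {
  data.table(file = paths, md5 = unname(tools::md5sum(paths)))
}

#' Run a named skim-seq pipeline
#'
#' @param name `"aneuploidy"`, `"introgression"` or `"genotyping"`.
#' @param config configuration list or YAML path. Common keys: `bins`
#'   (bin-count TSV), `out_dir`, `plots` (logical). Aneuploidy:
#'   `centromeres`, `sheet`, `band`. Introgression: `catalog`,
#'   `recipient_label`, `donor_label`, `mask`, `min_seg_bins`,
#'   `z_threshold`, `min_mb`, `baseline`. Genotyping: `parent_a`,
#'   `parent_b`, `progeny` (named pileup paths or a directory),
#'   `window_bp`, `min_markers`.
#' @return list with `outputs` (named paths), `manifest` (file + md5) and
#'   pipeline-specific result tables.
#' @export
run_pipeline <- function(name = c("aneuploidy", "introgression", "genotyping"),
                         config) {
  name <- match.arg(name)
  config <- read_run_config(config)
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bin_size <- cfg_get(config, "bin_size", 1e6)
  if (bin_size <= 0) stop("bin_size must be positive")
  message("[skimseqr] pipeline=", name, " out_dir=", out_dir)

  res <- switch(name,
    aneuploidy = pipeline_aneuploidy(config, out_dir),
    introgression = pipeline_introgression(config, out_dir),
    genotyping = pipeline_genotyping(config, out_dir))
  res$manifest <- manifest_entry(unlist(res$outputs))
  res
}

pipeline_aneuploidy <- function(config, out_dir) {
  bins <- read_bin_counts(cfg_get(config, "bins", required = TRUE))
  cen_path <- cfg_get(config, "centromeres")
  cen <- if (!is.null(cen_path)) read_centromeres(cen_path) else NULL
  sheet_path <- cfg_get(config, "sheet")
  sheet <- if (!is.null(sheet_path)) read_sample_sheet(sheet_path) else NULL

  flags <- detect_failed_and_blank(bin_totals(bins), sheet)
  usable <- flags[status == "ok", sample]
  profile <- compute_copy_ratio(
    bins, baseline = cfg_get(config, "baseline", "auto"),
    exclude_samples = flags[status != "ok", sample])
  karyo <- classify_dosage(profile, cen, band = cfg_get(config, "band", 0.15))
  karyo <- merge(karyo, flags[, .(sample, status)], by = "sample", all.x = TRUE)
  karyo[!(sample %in% usable), class_call := fifelse(
    status %in% c("blank_pass", "blank_fail"), "blank", "failed")]

  outs <- list(karyotype = file.path(out_dir, "karyotype.tsv"),
               qc = file.path(out_dir, "sample_qc.tsv"))
  fwrite(karyo, outs$karyotype, sep = "\t")
  fwrite(flags, outs$qc, sep = "\t")
  if (isTRUE(cfg_get(config, "plots", FALSE))) {
    cat_path <- cfg_get(config, "catalog")
    if (!is.null(cat_path)) {
      catal <- read_catalog(cat_path)
      pl <- file.path(out_dir, "karyogram.pdf")
      ggplot2::ggsave(pl, plot_karyogram(profile, catal, cen,
                                         samples = head(usable, 4),
                                         value = "ratio"),
                      width = 10, height = 8)
      outs$karyogram <- pl
    }
  }
  list(outputs = outs, karyotype = karyo, qc = flags)
}

pipeline_introgression <- function(config, out_dir) {
  bins <- read_bin_counts(cfg_get(config, "bins", required = TRUE))
  catal <- read_catalog(cfg_get(config, "catalog", required = TRUE))
  mask_path <- cfg_get(config, "mask")
  mask <- if (!is.null(mask_path)) read_mask_bed(mask_path) else NULL

  profile <- compute_copy_ratio(
    bins, baseline = cfg_get(config, "baseline", "self_genome_median"))
  segs <- segment_profile(profile, mask = mask,
                          min_seg_bins = cfg_get(config, "min_seg_bins", 3L),
                          z_threshold = cfg_get(config, "z_threshold", 4))
  calls <- pair_translocations(
    segs, catal,
    recipient_label = cfg_get(config, "recipient_label", required = TRUE),
    donor_label = cfg_get(config, "donor_label", required = TRUE),
    min_mb = cfg_get(config, "min_mb", 3))
  smry <- summarize_population(calls, all_samples = unique(profile$bins$sample),
                               by = "pair")

  outs <- list(segments = file.path(out_dir, "segments.tsv"),
               translocations = file.path(out_dir, "translocations.tsv"),
               segregation = file.path(out_dir, "segregation.tsv"))
  fwrite(segs, outs$segments, sep = "\t")
  fwrite(calls, outs$translocations, sep = "\t")
  fwrite(smry, outs$segregation, sep = "\t")
  list(outputs = outs, segments = segs, translocations = calls,
       segregation = smry)
}

pipeline_genotyping <- function(config, out_dir) {
  pa <- read_pileup(cfg_get(config, "parent_a", required = TRUE))
  pb <- read_pileup(cfg_get(config, "parent_b", required = TRUE))
  variants <- discover_parental_snps(
    pa, pb,
    min_dp = cfg_get(config, "min_dp", 6),
    max_dp = cfg_get(config, "max_dp", 100),
    min_allele_depth = cfg_get(config, "min_allele_depth", 3),
    min_purity = cfg_get(config, "min_purity", 0.9))

  prog <- cfg_get(config, "progeny", required = TRUE)
  if (length(prog) == 1L && dir.exists(prog)) {
    paths <- list.files(prog, pattern = "\\.tsv$", full.names = TRUE)
    prog <- setNames(paths, sub("\\.tsv$", "", basename(paths)))
  }
  calls <- rbindlist(lapply(names(prog), function(s)
    genotype_at_sites(read_pileup(prog[[s]]), variants, sample_id = s)))
  blocks <- call_haplotype_blocks(
    calls, window_bp = cfg_get(config, "window_bp", 5e6),
    min_markers = cfg_get(config, "min_markers", 3L),
    majority = cfg_get(config, "majority", 0.8))
  miss <- missingness_profile(calls)

  outs <- list(variants = file.path(out_dir, "parental_variants.tsv"),
               genotypes = file.path(out_dir, "genotypes.tsv"),
               blocks = file.path(out_dir, "haplotype_blocks.tsv"),
               missingness = file.path(out_dir, "missingness.tsv"))
  fwrite(variants, outs$variants, sep = "\t")
  write_genotype_matrix(calls, outs$genotypes)
  fwrite(blocks, outs$blocks, sep = "\t")
  fwrite(miss$per_sample, outs$missingness, sep = "\t")
  list(outputs = outs, variants = variants, calls = calls, blocks = blocks,
       missingness = miss)
}
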