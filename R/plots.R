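#' Karyogram and genotype plots
#'
#' A karyogram shows a sample's normalized read counts (or copy ratios)
#' along the concatenated chromosomes, with dashed vertical lines marking
#' centromeres; chromosome dosage and introgressed segments are read
#' directly off the track. The genotype plot paints each chromosome by the
#' parent assigned to sparse markers or haplotype blocks.
#'
#' @name plots
NULL

concat_coords <- function(catalog) {
  catalog <- validate_catalog(catalog)
  off <- cumsum(c(0, head(catalog$length_bp, -1)))
  data.table(chrom = catalog$contig_id, cum_offset = off,
             length_bp = catalog$length_bp)
}

#' Plot a karyogram
#'
#' @param x a `bin_counts` table or `dosage_profile`.
#' @param catalog the [genome_catalog()] (fixes chromosome order).
#' @param centromeres optional centromere table (dashed lines).
#' @param samples samples to plot (default: all, facetted).
#' @param value `"norm"` or `"ratio"` (ratio only for profiles).
#' @return a `ggplot` object.
#' @export
plot_karyogram <- function(x, catalog, centromeres = NULL, samples = NULL,
                           value = c("norm", "ratio")) {
  value <- match.arg(value)
  bins <- if (inherits(x, "dosage_profile")) x$bins else as.data.table(x)
  if (value == "ratio" && !"ratio" %in% names(bins))
    stop("ratio requested but input has no ratio column")
  if (!is.null(samples)) bins <- bins[sample %in% samples]
  cc <- concat_coords(catalog)
  bins <- merge(bins, cc, by = "chrom")
  bins[, x := cum_offset + (start + end) / 2]
  bins[, y := get(value)]

  p <- ggplot2::ggplot(bins, ggplot2::aes(x = x / 1e6, y = y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(cc$cum_offset,
                                       sum(catalog$length_bp)) / 1e6,
                        linewidth = 0.2, colour = "grey70") +
    ggplot2::labs(x = "concatenated position (Mb)",
                  y = if (value == "norm") "normalized reads / bin"
                      else "copy ratio") +
    ggplot2::theme_minimal()
  if (!is.null(centromeres)) {
    cen <- merge(validate_centromeres(centromeres),
                 cc, by.x = "contig_id", by.y = "chrom")
    p <- p + ggplot2::geom_vline(
      xintercept = (cen$cum_offset + cen$centromere_bp) / 1e6,
      linetype = "dashed", linewidth = 0.3)
  }
  if (uniqueN(bins$sample) > 1L)
    p <- p + ggplot2::facet_wrap(~sample, ncol = 1)
  p
}

#' Plot parental haplotype blocks along chromosomes
#'
#' @param blocks block table from [call_haplotype_blocks()].
#' @param catalog the [genome_catalog()].
#' @return a `ggplot` object.
#' @export
plot_haplotype_blocks <- function(blocks, catalog) {
  blocks <- as.data.table(blocks)
  catalog <- validate_catalog(catalog)
  blocks[, chrom := factor(chrom, levels = catalog$contig_id)]
  ggplot2::ggplot(blocks,
                  ggplot2::aes(xmin = start_bp / 1e6, xmax = end_bp / 1e6,
                               ymin = 0, ymax = 1, fill = parent)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(sample ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#1b9e77", B = "#d95f02",
                                          unresolved = "grey80")) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
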