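#' Binned read counts and coverage arithmetic
#'
#' The central analysis object is a long-format table of read counts per
#' fixed-width genomic bin (1 Mb by default) per sample. Raw counts are
#' normalized per sample as
#'
#' \deqn{\mathrm{norm} = \frac{\mathrm{reads\ in\ bin}}{\mathrm{total\ reads\ in\ sample}} \times F}
#'
#' with normalization factor \eqn{F} = 10 million by default, or alternatively
#' divided by the sample's mean count over all bins. Genome coverage of a
#' multiplexed pool is estimated as
#'
#' \deqn{\mathrm{coverage} = \frac{\mathrm{read\ count} \times \mathrm{read\ length} \times 2}{\mathrm{genome\ size} \times n_\mathrm{samples}}}
#'
#' where read count is the number of read pairs (the factor 2 accounts for
#' the two mates).
#'
#' @name bincount
NULL

#' Build a bin grid over a catalog
#'
#' Bins are 0-based half-open `[start, end)`, contiguous within each contig;
#' the last bin of a contig is truncated at the contig length.
#'
#' @param catalog a [genome_catalog()].
#' @param bin_size_bp bin width (default 1 Mb).
#' @return `data.table` with columns `chrom`, `start`, `end`; attribute
#'   `bin_size`.
#' @export
bin_grid <- function(catalog, bin_size_bp = 1e6) {
  catalog <- validate_catalog(catalog)
  stopifnot(bin_size_bp > 0)
  g <- catalog[, {
    s <- seq(0, length_bp - 1, by = bin_size_bp)
    .(start = s, end = pmin(s + bin_size_bp, length_bp))
  }, by = .(chrom = contig_id)]
  setattr(g, "bin_size", bin_size_bp)
  g[]
}

new_bin_counts <- function(bins, totals, unit, bin_size) {
  setattr(bins, "totals", totals)
  setattr(bins, "unit", unit)
  setattr(bins, "bin_size", bin_size)
  setattr(bins, "class", c("bin_counts", class(data.table())))
  bins[]
}

#' Per-sample totals of a bin-count table
#' @param x a `bin_counts` table.
#' @return named numeric vector of counted units per sample.
#' @export
bin_totals <- function(x) {
  tot <- attr(x, "totals")
  if (is.null(tot)) {
    t2 <- x[, .(total = sum(raw)), by = sample]
    tot <- setNames(t2$total, t2$sample)
  }
  tot
}

#' Count filtered alignments in bins
#'
#' With `unit = "pairs"` (the default) each template is counted once, in the
#' bin containing the leftmost mapped mate position; with `unit = "reads"`
#' each record is counted in its own bin. Alignments on contigs absent from
#' the grid go to an `unplaced` bucket reported via
#' `attr(result, "unplaced")`.
#'
#' @param aln SAM/BAM path or alignment table ([read_alignments()]); should
#'   already be filtered with [filter_unique_concordant()].
#' @param grid a [bin_grid()].
#' @param sample_id sample name for the output rows.
#' @param unit `"pairs"` or `"reads"`.
#' @return a `bin_counts` table (columns `sample`, `chrom`, `start`, `end`,
#'   `raw`, `norm` = NA) covering every grid bin, zero-filled.
#' @export
count_in_bins <- function(aln, grid, sample_id = "sample", unit = c("pairs", "reads")) {
  unit <- match.arg(unit)
  if (!is.data.frame(aln)) aln <- read_alignments(aln)
  aln <- as.data.table(aln)
  bin_size <- attr(grid, "bin_size")
  if (is.null(bin_size)) bin_size <- max(grid$end - grid$start)

  pts <- if (unit == "pairs") {
    aln[, .(rname = rname[which.min(pos)], pos = min(pos)), by = qname]
  } else {
    aln[, .(rname, pos)]
  }
  known <- pts$rname %in% unique(grid$chrom)
  n_unplaced <- sum(!known)
  pts <- pts[known]
  pts[, `:=`(chrom = rname, start = floor((pos - 1) / bin_size) * bin_size)]
  cnt <- pts[, .(raw = .N), by = .(chrom, start)]
  out <- merge(grid, cnt, by = c("chrom", "start"), all.x = TRUE)
  out[is.na(raw), raw := 0L]
  # clip counts whose bin start exceeds the truncated last bin
  out[, sample := sample_id]
  setcolorder(out, c("sample", "chrom", "start", "end", "raw"))
  out[, norm := NA_real_]
  setorder(out, chrom, start)
  tot <- setNames(sum(out$raw), sample_id)
  res <- new_bin_counts(out, tot, unit, bin_size)
  setattr(res, "unplaced", n_unplaced)
  if (n_unplaced > 0L)
    message(n_unplaced, " units on contigs absent from the grid (unplaced)")
  res
}

#' Combine per-sample bin counts
#' @param ... `bin_counts` tables.
#' @return a single `bin_counts` table.
#' @export
bind_bin_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.data.frame(xs[[1]])) xs <- xs[[1]]
  tot <- do.call(c, lapply(xs, bin_totals))
  out <- rbindlist(xs)
  new_bin_counts(out, tot, attr(xs[[1]], "unit"), attr(xs[[1]], "bin_size"))
}

#' Normalize bin counts
#'
#' `fixed_factor` mode: `norm = raw / total_units_in_sample * factor`.
#' `mean_bin` mode: `norm = raw / mean(raw over the sample's bins)`.
#' Samples with zero total get `norm = 0` everywhere and are flagged in
#' `attr(result, "failed_samples")`.
#'
#' @param x a `bin_counts` table.
#' @param mode `"fixed_factor"` or `"mean_bin"`.
#' @param factor normalization factor (default 1e7, i.e. reads per
#'   10 million).
#' @param totals optional named per-sample totals overriding the counted
#'   units (e.g. raw FASTQ read counts).
#' @return the table with `norm` filled.
#' @export
normalize_bin_counts <- function(x, mode = c("fixed_factor", "mean_bin"),
                                 factor = 1e7, totals = NULL) {
  mode <- match.arg(mode)
  stopifnot(factor > 0)
  x <- copy(x)
  if (is.null(totals)) totals <- bin_totals(x)
  failed <- character(0)
  if (mode == "fixed_factor") {
    x[, total := totals[sample]]
    x[, norm := ifelse(total > 0, raw / total * factor, 0)]
    failed <- names(totals)[totals <= 0]
    x[, total := NULL]
  } else {
    x[, norm := {
      m <- mean(raw)
      if (m > 0) raw / m else 0
    }, by = sample]
    failed <- x[, .(m = mean(raw)), by = sample][m <= 0, sample]
  }
  res <- new_bin_counts(x, totals, attr(x, "unit"), attr(x, "bin_size"))
  setattr(res, "norm_mode", mode)
  setattr(res, "norm_factor", if (mode == "fixed_factor") factor else NA_real_)
  setattr(res, "failed_samples", failed)
  res
}

#' Estimate pooled genome coverage
#'
#' `coverage = read_count * read_length * 2 / (genome_size * n_samples)`,
#' where `read_count` is the number of read pairs (spots) in the pool.
#'
#' @param read_count number of read pairs across the pool.
#' @param read_length_bp read length (default 150).
#' @param genome_size_bp genome size in bp.
#' @param n_samples number of multiplexed samples.
#' @return mean fold coverage per sample.
#' @export
estimate_coverage <- function(read_count, read_length_bp = 150,
                              genome_size_bp, n_samples) {
  stopifnot(read_count >= 0, read_length_bp > 0, genome_size_bp > 0,
            n_samples > 0)
  read_count * read_length_bp * 2 / (genome_size_bp * n_samples)
}

#' Effective depth from the mean pairs per bin
#'
#' Converts the observed mean number of read pairs per bin into fold
#' coverage: `mean_pairs_per_bin * 2 * read_length / bin_size`.
#'
#' @param mean_pairs_per_bin observed mean pairs per bin.
#' @param read_length_bp read length.
#' @param bin_size_bp bin width.
#' @return fold coverage.
#' @export
effective_depth_from_bin_mean <- function(mean_pairs_per_bin,
                                          read_length_bp = 150,
                                          bin_size_bp = 1e6) {
  stopifnot(mean_pairs_per_bin >= 0, read_length_bp > 0, bin_size_bp > 0)
  mean_pairs_per_bin * 2 * read_length_bp / bin_size_bp
}

#' Drop bins on unknown / unplaced contigs
#'
#' Removes rows whose contig matches any of the exclusion patterns
#' (case-insensitive regular expressions; default catches ids containing
#' "Un" or "unplaced").
#'
#' @param x a `bin_counts` table (or any table with a `chrom` column).
#' @param patterns character vector of regular expressions.
#' @return filtered table; `attr(result, "n_removed")` rows were dropped.
#' @export
drop_unknown_contigs <- function(x, patterns = c("Un", "unplaced")) {
  hit <- Reduce(`|`, lapply(patterns, function(p)
    grepl(p, x$chrom, ignore.case = TRUE)))
  out <- x[!hit]
  if (nrow(out) == 0L) stop("all rows matched the exclusion patterns")
  out <- new_bin_counts(out, attr(x, "totals"), attr(x, "unit"),
                        attr(x, "bin_size"))
  setattr(out, "n_removed", sum(hit))
  out
}

#' Per-chromosome read-density summary
#'
#' Mean raw (and normalized) count per bin for each contig, per sample and
#' population-wide; identifies the min/max density contigs.
#'
#' @param x a `bin_counts` table.
#' @return list with `per_sample`, `population` tables and `min_contig` /
#'   `max_contig` (by population mean raw density).
#' @export
per_chromosome_density <- function(x) {
  stopifnot(nrow(x) > 0)
  per_sample <- x[, .(mean_raw = mean(raw), mean_norm = mean(norm)),
                  by = .(sample, chrom)]
  population <- per_sample[, .(mean_raw = mean(mean_raw),
                               mean_norm = mean(mean_norm)), by = chrom]
  list(per_sample = per_sample[], population = population[],
       min_contig = population$chrom[which.min(population$mean_raw)],
       max_contig = population$chrom[which.max(population$mean_raw)])
}

#' Read / write bin-count TSVs
#'
#' Long format with header `sample  chrom  start  end  raw  norm` and
#' `#`-prefixed metadata lines recording the counting unit and normalization.
#'
#' @param x a `bin_counts` table.
#' @param path file path.
#' @export
write_bin_counts <- function(x, path) {
  meta <- c(
    paste0("# unit=", attr(x, "unit") %||% "pairs"),
    paste0("# bin_size=", attr(x, "bin_size") %||% ""),
    paste0("# norm_mode=", attr(x, "norm_mode") %||% ""),
    paste0("# norm_factor=", attr(x, "norm_factor") %||% "")
  )
  writeLines(meta, path)
  fwrite(x[, .(sample, chrom, start, end, raw, norm)], path, sep = "\t",
         append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  hdr <- readLines(path, n = 20L)
  meta_lines <- hdr[startsWith(hdr, "#")]
  x <- fread(path, sep = "\t", skip = length(meta_lines))
  meta <- function(key) {
    ln <- grep(paste0("^# ", key, "="), meta_lines, value = TRUE)
    if (!length(ln)) return(NULL)
    v <- sub(paste0("^# ", key, "="), "", ln[1])
    if (nzchar(v)) v else NULL
  }
  bs <- suppressWarnings(as.numeric(meta("bin_size")))
  res <- new_bin_counts(x, NULL, meta("unit") %||% "pairs",
                        if (length(bs) && !is.na(bs)) bs else max(x$end - x$start))
  tot <- x[, .(total = sum(raw)), by = sample]
  setattr(res, "totals", setNames(tot$total, tot$sample))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
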