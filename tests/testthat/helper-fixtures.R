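library(data.table)

# --- small catalogs -------------------------------------------------------

tiny_catalog <- function(lengths = c(chrA = 100e6, chrB = 250e6),
                         label = "wheat") {
  genome_catalog(names(lengths), unname(lengths), label)
}

# wheat group-7 + barley 7H hybrid, full Mb-scale lengths
group7_hybrid <- function() {
  wheat <- genome_catalog(paste0("wheat_chr7", c("A", "B", "D")),
                          c(736e6, 750e6, 638e6), "wheat",
                          original_id = paste0("chr7", c("A", "B", "D")))
  barley <- genome_catalog("barley_chr7H", 657e6, "barley",
                           original_id = "chr7H")
  validate_catalog(rbind(wheat, barley))
}

# --- sample sheets --------------------------------------------------------

demo_sheet <- function(n_samples = 6, n_blanks = 1) {
  i7 <- c("ACGTAC", "TTGGCA", "GATCGA", "CCAATT", "GGTACA", "TACGGT",
          "CGCGAT", "ATATGC", "GCGCTA", "TGCATG")[seq_len(n_samples + n_blanks)]
  data.table(
    sample_id = c(sprintf("s%02d", seq_len(n_samples)),
                  if (n_blanks > 0) sprintf("blank%d", seq_len(n_blanks))),
    plate_id = "P1",
    well = sprintf("A%02d", seq_len(n_samples + n_blanks)),
    i7 = i7,
    i5 = rep("AACCGG", n_samples + n_blanks),
    is_blank = c(rep(FALSE, n_samples), rep(TRUE, n_blanks)))
}

write_fastq_records <- function(path, ids, seqs, comments = NULL) {
  hdr <- if (is.null(comments)) paste0("@", ids)
         else paste0("@", ids, " ", comments)
  writeLines(as.vector(rbind(hdr, seqs, "+",
                             vapply(seqs, function(s) strrep("I", nchar(s)),
                                    character(1)))), path)
}

# --- SAM fixtures ---------------------------------------------------------

write_sam <- function(path, contigs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:",
                  format(contigs, scientific = FALSE, trim = TRUE)))
  writeLines(c(hdr, records), path)
}

sam_record <- function(qname, flag, rname, pos, mpos, tags = "NH:i:1\tYT:Z:CP",
                       read_len = 50) {
  base <- paste(qname, flag, rname, pos, 60, paste0(read_len, "M"), "=",
                mpos, ifelse(flag < 128, 300, -300),
                strrep("A", read_len), strrep("I", read_len), sep = "\t")
  if (nzchar(tags)) paste(base, tags, sep = "\t") else base
}

# --- dosage profile built directly from target ratios ---------------------

profile_from_ratios <- function(ratio_list, n_bins = 40, bin_size = 1e6,
                                sample_id = "s1") {
  bins <- rbindlist(lapply(names(ratio_list), function(cc) {
    r <- ratio_list[[cc]]
    if (length(r) == 1L) r <- rep(r, n_bins)
    data.table(sample = sample_id, chrom = cc,
               start = (seq_along(r) - 1) * bin_size,
               end = seq_along(r) * bin_size,
               norm = r * 100, ratio = r, baseline = "self")
  }))
  contigs <- bins[, .(mean_ratio = mean(ratio), n_bins = .N),
                  by = .(sample, chrom)]
  structure(list(bins = bins, contigs = contigs, bin_size = bin_size),
            class = "dosage_profile")
}

# --- exhaustive least-squares changepoint oracle --------------------------

seg_ss <- function(x, i, j) {
  s <- x[i:j]
  sum((s - mean(s))^2)
}

ls_oracle <- function(x, k, min_seg = 3L) {
  n <- length(x)
  if (k == 0L) return(integer(0))
  if (k == 1L) {
    cand <- (min_seg + 1L):(n - min_seg + 1L)
    ss <- vapply(cand, function(c1) seg_ss(x, 1, c1 - 1) + seg_ss(x, c1, n),
                 numeric(1))
    return(cand[which.min(ss)])
  }
  best <- NULL; best_ss <- Inf
  for (c1 in (min_seg + 1L):(n - 2L * min_seg + 1L)) {
    for (c2 in (c1 + min_seg):(n - min_seg + 1L)) {
      ss <- seg_ss(x, 1, c1 - 1) + seg_ss(x, c1, c2 - 1) + seg_ss(x, c2, n)
      if (ss < best_ss) { best_ss <- ss; best <- c(c1, c2) }
    }
  }
  best
}

# fraction of total genome length whose assigned block parent matches truth
fraction_true_parent <- function(blocks, truth) {
  blocks <- as.data.table(blocks); truth <- as.data.table(truth)
  tot <- 0; good <- 0
  for (s in unique(truth$sample)) {
    for (cc in unique(truth$chrom)) {
      tr <- truth[sample == s & chrom == cc]
      bb <- blocks[sample == s & chrom == cc]
      tot <- tot + max(tr$end_bp)
      if (!nrow(bb)) next
      for (i in seq_len(nrow(bb))) {
        if (!bb$parent[i] %in% c("A", "B")) next
        good <- good + tr[parent == bb$parent[i],
          sum(pmax(0, pmin(end_bp, bb$end_bp[i]) -
                      pmax(start_bp, bb$start_bp[i])))]
      }
    }
  }
  good / tot
}
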