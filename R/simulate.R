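#' Synthetic skim-seq data generation
#'
#' Every analysis step in the package can be exercised against synthetic
#' inputs with known ground truth. The signal model is deliberately the
#' simplest consistent with low-coverage whole-genome sequencing: read pairs
#' land uniformly on the genome, so the raw count of a bin of width `w` at
#' fold coverage `c` and copy number `k` is Poisson with mean
#'
#' \deqn{\lambda = \frac{c \, w}{2 \ell} \cdot \frac{k}{2}}
#'
#' where `l` is the read length (a pair contributes `2 l` sequenced bases).
#' With this convention [estimate_coverage()] applied to simulated totals
#' recovers the configured coverage. An optional negative-binomial
#' overdispersion hook is provided but off by default. All generators are
#' pure functions of their arguments and seed.
#'
#' @name simulate
NULL

with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Toy genome catalogs
#'
#' `toy_wheat_catalog()` builds a 21-chromosome hexaploid-wheat-like catalog
#' with approximate real pseudomolecule lengths (Mb scale) and submetacentric
#' centromeres; `toy_hybrid_catalog()` appends barley-like group-7 donor
#' chromosomes for translocation scenarios.
#'
#' @param scale length multiplier (1 = full Mb-scale lengths).
#' @return list with `catalog` ([genome_catalog()]) and `centromeres`.
#' @export
toy_wheat_catalog <- function(scale = 1) {
  chroms <- c("1A", "1B", "1D", "2A", "2B", "2D", "3A", "3B", "3D",
              "4A", "4B", "4D", "5A", "5B", "5D", "6A", "6B", "6D",
              "7A", "7B", "7D")
  len_mb <- c(594, 689, 495, 780, 801, 651, 750, 830, 615,
              744, 673, 509, 709, 713, 566, 618, 720, 473,
              736, 750, 638)
  cen_frac <- c(0.48, 0.45, 0.45, 0.45, 0.47, 0.47, 0.46, 0.45, 0.45,
                0.36, 0.44, 0.42, 0.36, 0.42, 0.33, 0.43, 0.44, 0.42,
                0.49, 0.42, 0.45)
  lens <- round(len_mb * 1e6 * scale)
  cat <- genome_catalog(paste0("chr", chroms), lens, "wheat",
                        original_id = paste0("chr", chroms))
  cen <- data.table(contig_id = cat$contig_id,
                    centromere_bp = round(lens * cen_frac))
  list(catalog = cat, centromeres = validate_centromeres(cen, cat))
}

#' @param donor_chroms donor contig original names.
#' @param donor_len_mb donor contig lengths in Mb.
#' @rdname toy_wheat_catalog
#' @export
toy_hybrid_catalog <- function(scale = 1, donor_chroms = "chr7H",
                               donor_len_mb = 657) {
  wb <- toy_wheat_catalog(scale)
  don <- genome_catalog(paste0("barley_", donor_chroms),
                        round(donor_len_mb * 1e6 * scale), "barley",
                        original_id = donor_chroms)
  wc <- copy(wb$catalog)[, contig_id := paste0("wheat_", contig_id)]
  wc[, source_genome := "wheat"]
  cen <- copy(wb$centromeres)[, contig_id := paste0("wheat_", contig_id)]
  cat <- validate_catalog(rbind(wc, don))
  list(catalog = cat, centromeres = validate_centromeres(cen, cat))
}

#' Specify a karyotype for simulation
#'
#' A karyotype is a table of copy-number overrides; any region not covered
#' by an override is disomic (copy 2). `start_bp`/`end_bp` of `NA` mean the
#' whole contig. Overlapping overrides are rejected.
#'
#' @param contig_id contig per override.
#' @param copy_number integer copy number (>= 0) per override.
#' @param start_bp,end_bp interval (0-based half-open) or `NA` for the whole
#'   contig.
#' @return `data.table` of class `sim_karyotype`.
#' @export
sim_karyotype <- function(contig_id = character(0), copy_number = integer(0),
                          start_bp = NA_real_, end_bp = NA_real_) {
  k <- data.table(contig_id = as.character(contig_id),
                  start_bp = as.numeric(start_bp),
                  end_bp = as.numeric(end_bp),
                  copy_number = as.numeric(copy_number))
  if (any(k$copy_number < 0)) stop("copy_number must be >= 0")
  if (nrow(k) > 1L) {
    for (cid in unique(k$contig_id)) {
      kk <- k[contig_id == cid]
      if (nrow(kk) > 1L) {
        if (any(is.na(kk$start_bp)))
          stop("whole-contig override overlaps another override on ", cid)
        setorder(kk, start_bp)
        if (any(kk$end_bp[-nrow(kk)] > kk$start_bp[-1]))
          stop("overlapping copy-number overrides on ", cid)
      }
    }
  }
  setattr(k, "class", c("sim_karyotype", class(data.table())))
  k[]
}

# expected copy number per bin under a karyotype (bin assigned the override
# covering its midpoint; overrides are bin-aligned in practice)
bin_copy_number <- function(grid, karyotype) {
  cp <- rep(2, nrow(grid))
  if (!is.null(karyotype) && nrow(karyotype)) {
    mid <- (grid$start + grid$end) / 2
    for (j in seq_len(nrow(karyotype))) {
      hit <- grid$chrom == karyotype$contig_id[j] &
        (is.na(karyotype$start_bp[j]) |
           (mid >= karyotype$start_bp[j] & mid < karyotype$end_bp[j]))
      cp[hit] <- karyotype$copy_number[j]
    }
  }
  cp
}

#' Simulate per-bin read-pair counts under a karyotype
#'
#' Each bin's raw count is drawn independently Poisson with mean
#' `coverage * width / (2 * read_length) * copy / 2` (negative binomial with
#' `size = 1/dispersion` when `dispersion` is given).
#'
#' @param karyotype a [sim_karyotype()] (or `NULL` for all-disomic).
#' @param catalog a [genome_catalog()].
#' @param coverage fold coverage of the sample (e.g. 0.01).
#' @param seed integer seed (required).
#' @param read_length_bp read length (default 150).
#' @param bin_size_bp bin width (default 1 Mb).
#' @param sample_id sample name.
#' @param dispersion optional negative-binomial overdispersion (NULL = pure
#'   Poisson).
#' @return a `bin_counts` table (raw filled, norm `NA`).
#' @export
simulate_bin_counts <- function(karyotype = NULL, catalog, coverage, seed,
                                read_length_bp = 150, bin_size_bp = 1e6,
                                sample_id = "sim", dispersion = NULL) {
  stopifnot(coverage >= 0, !missing(seed))
  grid <- bin_grid(catalog, bin_size_bp)
  cp <- bin_copy_number(grid, karyotype)
  lam <- coverage * (grid$end - grid$start) / (2 * read_length_bp) * cp / 2
  raw <- with_seed(seed, {
    if (is.null(dispersion)) rpois(length(lam), lam)
    else rnbinom(length(lam), mu = lam, size = 1 / dispersion)
  })
  out <- data.table(sample = sample_id, chrom = grid$chrom,
                    start = grid$start, end = grid$end, raw = raw,
                    norm = NA_real_)
  new_bin_counts(out, setNames(sum(raw), sample_id), "pairs", bin_size_bp)
}

#' Simulate a tagged SAM file of concordant read pairs
#'
#' Emulates the output of a spliced-alignment-disabled paired-end aligner:
#' pairs are placed uniformly within copy-weighted bins, written as two
#' records with proper-pair FLAGs; a fraction `multimapper_fraction` carries
#' `NH:i:2` (to be removed by [filter_unique_concordant()]), the rest
#' `NH:i:1`, and all carry `YT:Z:CP`. The returned truth counts are the
#' per-bin unique-pair counts, so running the filter and [count_in_bins()]
#' on the file reproduces them exactly.
#'
#' @inheritParams simulate_bin_counts
#' @param out_sam output SAM path.
#' @param multimapper_fraction fraction of pairs emitted with `NH:i:2`.
#' @param fragment_bp template length (default 300).
#' @return list with `sam` (path), `truth` (`bin_counts` of unique pairs),
#'   `n_pairs`, `n_multi`.
#' @export
simulate_sam <- function(karyotype = NULL, catalog, coverage, seed, out_sam,
                         read_length_bp = 150, bin_size_bp = 1e6,
                         sample_id = "sim", multimapper_fraction = 0,
                         fragment_bp = 300) {
  catalog <- validate_catalog(catalog)
  if (any(catalog$length_bp < fragment_bp))
    stop("contigs shorter than the fragment length")
  grid <- bin_grid(catalog, bin_size_bp)
  cp <- bin_copy_number(grid, karyotype)
  lam <- coverage * (grid$end - grid$start) / (2 * read_length_bp) * cp / 2

  sim <- with_seed(seed, {
    n_per_bin <- rpois(length(lam), lam)
    tot <- sum(n_per_bin)
    bin_idx <- rep(seq_along(n_per_bin), n_per_bin)
    len <- catalog$length_bp[match(grid$chrom[bin_idx], catalog$contig_id)]
    lo <- grid$start[bin_idx]
    hi <- pmin(grid$end[bin_idx], len - fragment_bp)
    pos1 <- floor(lo + runif(tot) * pmax(hi - lo, 1)) + 1  # 1-based leftmost
    multi <- runif(tot) < multimapper_fraction
    list(bin_idx = bin_idx, pos1 = pos1, multi = multi)
  })
  bin_idx <- sim$bin_idx; pos1 <- sim$pos1; multi <- sim$multi
  chrom <- grid$chrom[bin_idx]
  pos2 <- pos1 + fragment_bp - read_length_bp
  qname <- sprintf("p%07d", seq_along(pos1))
  nh <- ifelse(multi, 2L, 1L)
  seq_str <- strrep("A", read_length_bp)
  qual_str <- strrep("I", read_length_bp)
  cigar <- paste0(read_length_bp, "M")

  rec <- function(q, flag, ch, p, mp, tlen, nh) {
    paste(q, flag, ch, p, ifelse(nh == 1L, 60L, 1L), cigar, "=", mp, tlen,
          seq_str, qual_str, paste0("NH:i:", nh), "YT:Z:CP", sep = "\t")
  }
  r1 <- rec(qname, 99L, chrom, pos1, pos2, fragment_bp, nh)
  r2 <- rec(qname, 147L, chrom, pos2, pos1, -fragment_bp, nh)
  # coordinate order: sort all records by (contig, pos)
  allpos <- c(pos1, pos2)
  allchr <- c(chrom, chrom)
  lines <- c(r1, r2)
  o <- order(match(allchr, catalog$contig_id), allpos)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", catalog$contig_id, "\tLN:",
                  format(catalog$length_bp, scientific = FALSE, trim = TRUE)))
  writeLines(c(hdr, lines[o]), out_sam)

  # truth: unique pairs per bin
  tr <- data.table(bin = bin_idx[!multi])
  cnt <- tr[, .N, by = bin]
  raw <- integer(nrow(grid))
  raw[cnt$bin] <- cnt$N
  truth <- data.table(sample = sample_id, chrom = grid$chrom,
                      start = grid$start, end = grid$end, raw = raw,
                      norm = NA_real_)
  truth <- new_bin_counts(truth, setNames(sum(raw), sample_id), "pairs",
                          bin_size_bp)
  list(sam = out_sam, truth = truth, n_pairs = length(pos1),
       n_multi = sum(multi))
}

#' Simulate a monosomic-derived aneuploid panel
#'
#' Emulates the progeny of a chromosome-5D monosomic: each sample draws a
#' truth class and the matching karyotype on the target chromosome
#' (telosomics have one arm at copy 0 and the other at the stated copy,
#' split at the centromere). `failed` samples are simulated at a small
#' fraction of the nominal coverage and `blank` samples at (near) zero.
#' The default composition is the observed composition of an 864-line
#' monosomic-5D panel: 674 monosomic, 130 disomic, 35 long-arm telosomic,
#' 1 short-arm telosomic, 10 nullisomic, 5 failed, 9 blank.
#'
#' @param catalog,centromeres coordinate frame (defaults:
#'   [toy_wheat_catalog()]).
#' @param target_contig the segregating chromosome (default `"chr5D"`).
#' @param composition named integer vector over
#'   `disomic`, `monosomic`, `nullisomic`, `telosomic_long_arm`,
#'   `telosomic_short_arm`, `mono_plus_telo`, `trisomic`, `failed`, `blank`.
#' @param coverage nominal fold coverage (default 0.01).
#' @param failed_coverage_fraction coverage multiplier for failed samples
#'   (default 0.02, i.e. 2% of nominal).
#' @param seed integer seed.
#' @inheritParams simulate_bin_counts
#' @return list with `counts` (normalized `bin_counts` for all samples),
#'   `truth` (`sample`, `class`), `catalog`, `centromeres`, `target_contig`.
#' @export
simulate_monosomic_panel <- function(catalog = NULL, centromeres = NULL,
                                     target_contig = "chr5D",
                                     composition = c(disomic = 130,
                                                     monosomic = 674,
                                                     nullisomic = 10,
                                                     telosomic_long_arm = 35,
                                                     telosomic_short_arm = 1,
                                                     failed = 5, blank = 9),
                                     coverage = 0.01,
                                     failed_coverage_fraction = 0.02,
                                     seed, read_length_bp = 150,
                                     bin_size_bp = 1e6) {
  if (is.null(catalog)) {
    toy <- toy_wheat_catalog()
    catalog <- toy$catalog
    if (is.null(centromeres)) centromeres <- toy$centromeres
  }
  catalog <- validate_catalog(catalog)
  known <- c("disomic", "monosomic", "nullisomic", "telosomic_long_arm",
             "telosomic_short_arm", "mono_plus_telo", "trisomic",
             "failed", "blank")
  if (!all(names(composition) %in% known))
    stop("unknown classes in composition: ",
         paste(setdiff(names(composition), known), collapse = ", "))
  needs_cen <- c("telosomic_long_arm", "telosomic_short_arm", "mono_plus_telo")
  if (any(composition[intersect(names(composition), needs_cen)] > 0) &&
      (is.null(centromeres) || !target_contig %in% centromeres$contig_id))
    stop("telosomic classes require a centromere for ", target_contig)
  cen_bp <- if (!is.null(centromeres))
    centromeres$centromere_bp[match(target_contig, centromeres$contig_id)]
  else NA_real_
  clen <- catalog$length_bp[match(target_contig, catalog$contig_id)]

  classes <- rep(names(composition), composition)
  n <- length(classes)
  ids <- sprintf("s%04d", seq_len(n))

  kary_for <- function(cls) {
    switch(cls,
      disomic = NULL, failed = NULL, blank = NULL,
      monosomic = sim_karyotype(target_contig, 1),
      nullisomic = sim_karyotype(target_contig, 0),
      trisomic = sim_karyotype(target_contig, 3),
      telosomic_long_arm = sim_karyotype(rep(target_contig, 2), c(0, 1),
                                         c(0, cen_bp), c(cen_bp, clen)),
      telosomic_short_arm = sim_karyotype(rep(target_contig, 2), c(1, 0),
                                          c(0, cen_bp), c(cen_bp, clen)),
      mono_plus_telo = sim_karyotype(rep(target_contig, 2), c(1, 2),
                                     c(0, cen_bp), c(cen_bp, clen)),
      stop("unhandled class ", cls))
  }
  cov_for <- function(cls) {
    if (cls == "blank") 0
    else if (cls == "failed") coverage * failed_coverage_fraction
    else coverage
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    counts[[i]] <- simulate_bin_counts(
      kary_for(classes[i]), catalog, cov_for(classes[i]), seed = seeds[i],
      read_length_bp = read_length_bp, bin_size_bp = bin_size_bp,
      sample_id = ids[i])
  }
  all_counts <- bind_bin_counts(counts)
  all_counts <- normalize_bin_counts(all_counts)
  list(counts = all_counts,
       truth = data.table(sample = ids, class = classes),
       catalog = catalog, centromeres = centromeres,
       target_contig = target_contig)
}

#' Simulate a BC1 population segregating for a translocation
#'
#' Each sample is a translocation carrier with probability `carrier_prob`
#' (heterozygous: recipient interval at copy 1 and donor interval at copy
#' 1); non-carriers are euploid with no donor signal. Donor chromatin
#' outside the donor interval is always absent.
#'
#' @param catalog hybrid [genome_catalog()].
#' @param recipient_contig,recipient_start_bp,recipient_end_bp the recipient
#'   interval lost in carriers.
#' @param donor_contig,donor_start_bp,donor_end_bp the donor interval gained
#'   in carriers.
#' @param n_samples population size (default 335).
#' @param carrier_prob carrier probability (default 0.5, the BC1
#'   expectation).
#' @inheritParams simulate_bin_counts
#' @return list with `counts` (normalized), `truth` (`sample`, `carrier`),
#'   `catalog`.
#' @export
simulate_bc1_population <- function(catalog,
                                    recipient_contig, recipient_start_bp,
                                    recipient_end_bp,
                                    donor_contig, donor_start_bp,
                                    donor_end_bp,
                                    n_samples = 335, carrier_prob = 0.5,
                                    coverage = 0.025, seed,
                                    read_length_bp = 150, bin_size_bp = 1e6) {
  catalog <- validate_catalog(catalog)
  ids <- sprintf("bc%04d", seq_len(n_samples))
  drawn <- with_seed(seed, list(
    carrier = runif(n_samples) < carrier_prob,
    seeds = sample.int(.Machine$integer.max - 1L, n_samples)))
  kary_carrier <- sim_karyotype(
    contig_id = c(recipient_contig, donor_contig, donor_contig, donor_contig),
    copy_number = c(1, 0, 1, 0),
    start_bp = c(recipient_start_bp, 0, donor_start_bp, donor_end_bp),
    end_bp = c(recipient_end_bp, donor_start_bp, donor_end_bp,
               catalog$length_bp[match(donor_contig, catalog$contig_id)]))
  kary_noncarrier <- sim_karyotype(donor_contig, 0)
  counts <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    counts[[i]] <- simulate_bin_counts(
      if (drawn$carrier[i]) kary_carrier else kary_noncarrier,
      catalog, coverage, seed = drawn$seeds[i],
      read_length_bp = read_length_bp, bin_size_bp = bin_size_bp,
      sample_id = ids[i])
  }
  all_counts <- normalize_bin_counts(bind_bin_counts(counts))
  list(counts = all_counts,
       truth = data.table(sample = ids, carrier = drawn$carrier),
       catalog = catalog)
}

#' Simulate a doubled-haploid population with sparse genotypes
#'
#' Per sample and chromosome, the number of crossovers is Poisson
#' (`crossover_mean_per_chrom`), breakpoints are uniform, and the parental
#' phase alternates from a random starting parent. Each marker is observed
#' when at least one read covers it: observation probability
#' `1 - exp(-coverage)` (Poisson depth with mean equal to the fold
#' coverage); an observed marker yields the phase allele (error-free).
#'
#' @param marker_map `data.table` with `chrom`, `pos` (sorted marker
#'   positions), e.g. from [sim_marker_map()].
#' @param catalog a [genome_catalog()] giving chromosome lengths.
#' @param n_samples number of DH lines.
#' @param coverage fold coverage per sample.
#' @param crossover_mean_per_chrom mean crossovers per chromosome
#'   (default 2).
#' @param seed integer seed.
#' @return list with `calls` (sparse genotype calls, all samples), `truth`
#'   (haplotype intervals: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `parent`), `marker_map`.
#' @export
simulate_dh_population <- function(marker_map, catalog, n_samples,
                                   coverage, crossover_mean_per_chrom = 2,
                                   seed) {
  catalog <- validate_catalog(catalog)
  mm <- as.data.table(marker_map)
  setorder(mm, chrom, pos)
  p_obs <- 1 - exp(-coverage)
  ids <- sprintf("dh%03d", seq_len(n_samples))

  with_seed(seed, {
    truth_list <- list(); call_list <- list()
    for (i in seq_len(n_samples)) {
      for (cid in unique(mm$chrom)) {
        len <- catalog$length_bp[match(cid, catalog$contig_id)]
        k <- rpois(1, crossover_mean_per_chrom)
        brk <- sort(runif(k, 0, len))
        bounds <- c(0, brk, len)
        first <- sample(c("A", "B"), 1)
        pars <- rep(c(first, setdiff(c("A", "B"), first)),
                    length.out = length(bounds) - 1L)
        truth_list[[length(truth_list) + 1L]] <- data.table(
          sample = ids[i], chrom = cid,
          start_bp = bounds[-length(bounds)], end_bp = bounds[-1],
          parent = pars)
        pos <- mm[chrom == cid, pos]
        phase <- pars[findInterval(pos, bounds, rightmost.closed = TRUE)]
        obs <- runif(length(pos)) < p_obs
        call_list[[length(call_list) + 1L]] <- data.table(
          sample = ids[i], chrom = cid, pos = pos,
          call = ifelse(obs, phase, "missing"),
          n_A = as.integer(obs & phase == "A"),
          n_B = as.integer(obs & phase == "B"))
      }
    }
    list(calls = rbindlist(call_list), truth = rbindlist(truth_list),
         marker_map = mm)
  })
}

#' Evenly spaced marker positions over a catalog
#' @param catalog a [genome_catalog()].
#' @param spacing_bp marker spacing (default 10 kb).
#' @return `data.table` with `chrom`, `pos`.
#' @export
sim_marker_map <- function(catalog, spacing_bp = 1e4) {
  catalog <- validate_catalog(catalog)
  catalog[, .(pos = seq(spacing_bp, length_bp - 1, by = spacing_bp)),
          by = .(chrom = contig_id)]
}

random_dna <- function(n, len) {
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

add_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  hit <- matrix(runif(length(m)) < error_rate, nrow = nrow(m))
  if (any(hit)) {
    cur <- m[hit]
    m[hit] <- vapply(cur, function(b) sample(setdiff(BASES, b), 1),
                     character(1))
  }
  apply(m, 1, paste0, collapse = "")
}

#' Simulate multiplexed FASTQ files with index reads
#'
#' Writes R1/R2 read FASTQs plus I1 (i7) and I2 (i5) index FASTQs for every
#' non-blank sample in the sheet; blanks receive zero reads. Index reads
#' copy the sample's barcodes with per-base substitution errors at
#' `error_rate`; the i5 is written in the requested orientation. Records
#' from all samples are shuffled together as on a real flow cell.
#'
#' @param sheet a sample sheet.
#' @param out_dir output directory (files `R1.fastq`, `R2.fastq`,
#'   `I1.fastq`, `I2.fastq`).
#' @param reads_per_sample pairs per non-blank sample (default 50).
#' @param error_rate index-read substitution rate (default 0).
#' @param orientation how to write the i5 index reads.
#' @param read_length_bp genomic read length (default 60).
#' @param seed integer seed.
#' @return list with `files` (named paths) and `truth` (per-sample pair
#'   counts).
#' @export
simulate_index_reads <- function(sheet, out_dir, reads_per_sample = 50,
                                 error_rate = 0,
                                 orientation = c("as-is", "reverse-complement"),
                                 read_length_bp = 60, seed) {
  orientation <- match.arg(orientation)
  sheet <- validate_sample_sheet(sheet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  live <- sheet[is_blank == FALSE]
  n <- nrow(live) * reads_per_sample

  with_seed(seed, {
    src <- rep(seq_len(nrow(live)), each = reads_per_sample)
    src <- src[sample.int(n)]
    ids <- sprintf("read%06d", seq_len(n))
    i7 <- add_substitutions(live$i7[src], error_rate)
    i5_seq0 <- if (orientation == "reverse-complement") revcomp_chr(live$i5[src])
               else live$i5[src]
    i5 <- add_substitutions(i5_seq0, error_rate)
    r1 <- random_dna(n, read_length_bp)
    r2 <- random_dna(n, read_length_bp)

    wq <- function(seqs, path) {
      qs <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs),
        Biostrings::PhredQuality(strrep("I", nchar(seqs[1]))))
      names(qs) <- ids
      write_fastq(qs, path)
    }
    files <- c(R1 = file.path(out_dir, "R1.fastq"),
               R2 = file.path(out_dir, "R2.fastq"),
               I1 = file.path(out_dir, "I1.fastq"),
               I2 = file.path(out_dir, "I2.fastq"))
    wq(r1, files["R1"]); wq(r2, files["R2"])
    wq(i7, files["I1"]); wq(i5, files["I2"])
    truth <- merge(sheet[, .(sample_id, is_blank)],
                   data.table(sample_id = live$sample_id[src])[, .N, by = sample_id],
                   by = "sample_id", all.x = TRUE)
    truth[is.na(N), N := 0L]
    setnames(truth, "N", "n_pairs")
    list(files = files, truth = truth[])
  })
}
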