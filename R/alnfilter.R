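#' Alignment filtering and down-sampling
#'
#' Skim-seq karyotyping counts only uniquely mapped, concordant read pairs.
#' With a spliced-alignment-disabled paired-end aligner these are the records
#' carrying the SAM tags `NH:i:1` (single reported hit) and `YT:Z:CP`
#' (concordantly aligned pair); we additionally require the mapped, primary,
#' non-supplementary and proper-pair FLAG bits. Down-sampling draws an exact
#' number of read pairs without replacement so that coverage titrations
#' (e.g. 0.1x / 0.05x / 0.01x) are exactly sized and reproducible by seed.
#'
#' @name alnfilter
NULL

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

flag_has <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

sam_to_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE)
  } else path
}

#' Read alignments into a table
#'
#' Loads a SAM or BAM file (SAM is converted on the fly) into a `data.table`
#' with the fields and tags the binning and filtering steps need.
#'
#' @param path SAM or BAM file.
#' @return `data.table` with columns `qname`, `flag`, `rname`, `pos`,
#'   `NH`, `YT`.
#' @export
read_alignments <- function(path) {
  bam <- sam_to_bam(path)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos"),
                               tag = c("NH", "YT"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.table(qname = x$qname, flag = x$flag,
             rname = as.character(x$rname), pos = x$pos,
             NH = if (is.null(x$tag$NH)) NA_integer_ else x$tag$NH,
             YT = if (is.null(x$tag$YT)) NA_character_ else x$tag$YT)
}

keep_unique_concordant <- function(aln) {
  no_tags <- is.na(aln$NH) & is.na(aln$YT)
  keep <- !flag_has(aln$flag, FLAG_UNMAPPED) &
    !flag_has(aln$flag, FLAG_SECONDARY) &
    !flag_has(aln$flag, FLAG_SUPPLEMENTARY) &
    flag_has(aln$flag, FLAG_PROPER) &
    !is.na(aln$NH) & aln$NH == 1L &
    !is.na(aln$YT) & aln$YT == "CP"
  list(keep = keep & !no_tags, no_tags = no_tags)
}

#' Select uniquely mapped concordant records
#'
#' Keeps a record iff it is mapped, primary, non-supplementary, in a proper
#' pair, and carries `NH:i:1` and `YT:Z:CP`. Records missing both tags (other
#' aligners) are dropped with a warning and counted separately rather than
#' guessed from MAPQ. Input record order is preserved in the output.
#'
#' @param input SAM/BAM path, or a `data.table` from [read_alignments()].
#' @param output optional path for the filtered file (`.bam` or `.sam`);
#'   only used for file input.
#' @return list with `input_records`, `kept_records`, `dropped_no_tags`,
#'   and either `alignments` (table input) or `output` (file input).
#' @export
filter_unique_concordant <- function(input, output = NULL) {
  if (is.data.frame(input)) {
    aln <- as.data.table(input)
    kk <- keep_unique_concordant(aln)
    if (any(kk$no_tags))
      warning(sum(kk$no_tags), " records lack both NH and YT tags; dropped")
    return(list(input_records = nrow(aln), kept_records = sum(kk$keep),
                dropped_no_tags = sum(kk$no_tags),
                alignments = aln[kk$keep]))
  }
  bam <- sam_to_bam(input)
  if (is.null(output)) output <- sub("\\.(bam|sam)$", ".filtered.bam", input)
  p <- Rsamtools::ScanBamParam(what = c("flag"), tag = c("NH", "YT"))
  n_no_tags <- 0L
  rules <- S4Vectors::FilterRules(list(uc = function(df) {
    no_tags <- is.na(df$NH) & is.na(df$YT)
    n_no_tags <<- n_no_tags + sum(no_tags)
    !flag_has(df$flag, FLAG_UNMAPPED) &
      !flag_has(df$flag, FLAG_SECONDARY) &
      !flag_has(df$flag, FLAG_SUPPLEMENTARY) &
      flag_has(df$flag, FLAG_PROPER) &
      !is.na(df$NH) & df$NH == 1L & !is.na(df$YT) & df$YT == "CP"
  }))
  want_sam <- grepl("\\.sam$", output, ignore.case = TRUE)
  bam_out <- if (want_sam) tempfile(fileext = ".bam") else output
  Rsamtools::filterBam(bam, bam_out, param = p, filter = rules,
                       indexDestination = FALSE)
  if (want_sam)
    Rsamtools::asSam(bam_out, sub("\\.sam$", "", output), overwrite = TRUE)
  n_in <- Rsamtools::countBam(bam)$records
  n_kept <- Rsamtools::countBam(bam_out)$records
  if (n_no_tags > 0L)
    warning(n_no_tags, " records lack both NH and YT tags; dropped")
  list(input_records = n_in, kept_records = n_kept,
       dropped_no_tags = n_no_tags, output = output)
}

resolve_fraction <- function(fraction, target_coverage, current_coverage) {
  if (is.null(fraction) == is.null(target_coverage))
    stop("give exactly one of fraction / target_coverage")
  if (!is.null(target_coverage)) {
    if (is.null(current_coverage))
      stop("target_coverage requires current_coverage (see estimate_coverage)")
    if (target_coverage > current_coverage)
      stop("target coverage exceeds current coverage")
    fraction <- target_coverage / current_coverage
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  fraction
}

sample_exact <- function(n, fraction, seed) {
  k <- round(fraction * n)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sort(sample.int(n, k))
}

#' Down-sample read pairs
#'
#' Draws exactly `round(fraction * N)` read pairs without replacement, keeping
#' mates together; identical seed and input give identical output. Instead of
#' a fraction, a `target_coverage` may be given together with the
#' `current_coverage` of the input (e.g. from [estimate_coverage()]), in which
#' case `fraction = target_coverage / current_coverage`.
#'
#' @param r1,r2 input FASTQ paths.
#' @param out1,out2 output FASTQ paths.
#' @param fraction fraction of pairs to keep, in (0, 1].
#' @param target_coverage,current_coverage alternative specification.
#' @param seed integer seed (required).
#' @return list with `n_in`, `n_out`, `fraction`.
#' @export
downsample_fastq <- function(r1, r2, out1, out2, fraction = NULL,
                             target_coverage = NULL, current_coverage = NULL,
                             seed) {
  stopifnot(!missing(seed))
  fraction <- resolve_fraction(fraction, target_coverage, current_coverage)
  fq1 <- read_fastq(r1); fq2 <- read_fastq(r2)
  if (length(fq1) != length(fq2)) stop("R1/R2 have different record counts")
  idx <- sample_exact(length(fq1), fraction, seed)
  write_fastq(fq1[idx], out1)
  write_fastq(fq2[idx], out2)
  list(n_in = length(fq1), n_out = length(idx), fraction = fraction)
}

#' Down-sample an alignment file by read pair
#'
#' Samples whole templates (by read name) so mates stay together.
#'
#' @param input SAM/BAM path.
#' @param output BAM output path.
#' @inheritParams downsample_fastq
#' @return list with `n_pairs_in`, `n_pairs_out`, `fraction`, `output`.
#' @export
downsample_alignments <- function(input, output, fraction = NULL,
                                  target_coverage = NULL,
                                  current_coverage = NULL, seed) {
  stopifnot(!missing(seed))
  fraction <- resolve_fraction(fraction, target_coverage, current_coverage)
  bam <- sam_to_bam(input)
  qn <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname
  uq <- unique(qn)
  keep_q <- uq[sample_exact(length(uq), fraction, seed)]
  keep_set <- new.env(hash = TRUE, size = length(keep_q))
  for (q in keep_q) assign(q, TRUE, envir = keep_set)
  rules <- S4Vectors::FilterRules(list(ds = function(df) {
    vapply(df$qname, function(q) !is.null(keep_set[[q]]), logical(1))
  }))
  Rsamtools::filterBam(bam, output,
                       param = Rsamtools::ScanBamParam(what = "qname"),
                       filter = rules, indexDestination = FALSE)
  list(n_pairs_in = length(uq), n_pairs_out = length(keep_q),
       fraction = fraction, output = output)
}
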