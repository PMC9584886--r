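#' Dual-index demultiplexing
#'
#' Multiplexed skim-seq libraries use combinatorial dual indexes: one i5 index
#' per 96-well plate and one i7 index per sample within the plate, so a few
#' dozen barcodes address hundreds to thousands of samples. Depending on the
#' sequencing machine the i5 index may come off the instrument as the reverse
#' complement of the sample sheet, so orientation is detected once per run.
#' Each plate carries a blank well as a negative control; a blank passes QC
#' when it receives less than 0.01% of the mean reads per (non-blank) sample.
#'
#' @name demux
NULL

#' Read and validate a sample sheet
#'
#' Tab-delimited with header columns `sample_id`, `plate_id`, `well`, `i7`,
#' `i5`, `is_blank`.
#'
#' @param path sheet TSV path.
#' @return validated `data.table` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sh <- fread(path, sep = "\t", colClasses = list(character = 1:5))
  validate_sample_sheet(sh)
}

#' @param sheet a sample-sheet `data.frame`.
#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet) {
  sh <- as.data.table(sheet)
  need <- c("sample_id", "plate_id", "well", "i7", "i5", "is_blank")
  if (!all(need %in% names(sh)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sh[, is_blank := as.logical(is_blank)]
  if (anyDuplicated(sh$sample_id))
    stop("duplicate sample_id in sheet")
  if (anyDuplicated(sh[, .(i7, i5)]))
    stop("duplicate (i7, i5) barcode pair in sheet")
  if (length(unique(nchar(sh$i7))) != 1L || length(unique(nchar(sh$i5))) != 1L)
    stop("all i7 (and all i5) barcodes must have equal length")
  if (any(grepl("[^ACGT]", c(sh$i7, sh$i5))))
    stop("barcodes must be over the alphabet A,C,G,T")
  setattr(sh, "class", c("sample_sheet", class(data.table())))
  sh[]
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance from each string in `reads` to each barcode (equal length).
hamming_to_barcodes <- function(reads, barcodes) {
  u <- unique(reads)
  L <- nchar(barcodes[1])
  m <- matrix(unlist(strsplit(u, "", fixed = TRUE), use.names = FALSE),
              nrow = length(u), ncol = L, byrow = TRUE)
  d <- vapply(barcodes, function(b) {
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    as.integer(rowSums(m != matrix(bv, nrow = nrow(m), ncol = L, byrow = TRUE)))
  }, integer(length(u)))
  d <- matrix(d, nrow = length(u))
  d[match(reads, u), , drop = FALSE]
}

#' Detect the i5 index orientation
#'
#' Compares the exact-match rate of sampled i5 index reads against the sheet
#' barcodes as written and against their reverse complement, and returns the
#' orientation with the higher rate (ties resolve to `as-is`; zero matches in
#' both orientations warns and returns `as-is`).
#'
#' @param i5_reads character vector of i5 index-read sequences (a sample,
#'   typically the first 10,000 reads of I2).
#' @param sheet a validated sample sheet.
#' @return `"as-is"` or `"reverse-complement"`.
#' @export
detect_i5_orientation <- function(i5_reads, sheet) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(length(i5_reads) >= 1L)
  fwd <- sum(i5_reads %in% unique(sheet$i5))
  rev <- sum(i5_reads %in% unique(revcomp_chr(sheet$i5)))
  if (fwd == 0L && rev == 0L) {
    warning("no i5 index reads match the sheet in either orientation")
    return("as-is")
  }
  if (rev > fwd) "reverse-complement" else "as-is"
}

# Biostrings warns that (unused) mcols are dropped when quality-scaled sets
# are built or subset; irrelevant for plain FASTQ records
quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

read_fastq <- function(path) {
  quiet_mcols(Biostrings::readQualityScaledDNAStringSet(path))
}

fastq_ids <- function(x) sub("\\s.*$", "", names(x))

write_fastq <- function(x, path) {
  quiet_mcols(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

# Assign each (i7, i5) read pair to a sheet row.
# Returns integer vector: row index, 0 = undetermined.
match_barcodes <- function(i7_reads, i5_reads, sheet, max_mismatch) {
  d7 <- hamming_to_barcodes(i7_reads, sheet$i7)
  d5 <- hamming_to_barcodes(i5_reads, sheet$i5)
  ok <- d7 <= max_mismatch & d5 <= max_mismatch
  dtot <- d7 + d5
  dtot[!ok] <- NA_integer_
  assign1 <- function(i) {
    row <- dtot[i, ]
    if (all(is.na(row))) return(0L)
    b <- min(row, na.rm = TRUE)
    hits <- which(!is.na(row) & row == b)
    if (length(hits) != 1L) 0L else hits  # ambiguity rejection
  }
  vapply(seq_len(nrow(dtot)), assign1, integer(1))
}

#' Demultiplex paired-end reads by dual index
#'
#' Routes each read pair to exactly one sample (or to `undetermined`) by
#' per-index Hamming distance; a pair matching two or more samples at the
#' winning distance is rejected as ambiguous. Index sequences come either
#' from separate I1/I2 FASTQ files or, when `i1`/`i2` are `NULL`, from the
#' read-header comment field in the layout `...:<i7>+<i5>`.
#'
#' @param r1,r2 paths to the paired read FASTQs.
#' @param i1,i2 paths to index-read FASTQs (i7 and i5), or `NULL` to parse
#'   barcodes from the R1 headers.
#' @param sheet sample sheet (path or table).
#' @param out_dir directory for per-sample FASTQs (`<sample>_R1.fastq`, ...)
#'   plus `undetermined_R[12].fastq`.
#' @param max_mismatch maximum Hamming distance per index (default 0,
#'   exact matching).
#' @param orientation `"auto"` (detect from the first 10,000 i5 reads),
#'   `"as-is"` or `"reverse-complement"`.
#' @return a `skim_demux_report`: list with `counts` (per-sample pairs),
#'   `undetermined`, `total`, `orientation`, and `blanks` (see
#'   [check_blanks()]).
#' @export
demultiplex <- function(r1, r2, i1 = NULL, i2 = NULL, sheet, out_dir,
                        max_mismatch = 0L,
                        orientation = c("auto", "as-is", "reverse-complement")) {
  orientation <- match.arg(orientation)
  if (is.character(sheet) && length(sheet) == 1L) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  stopifnot(max_mismatch >= 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fq1 <- read_fastq(r1)
  fq2 <- read_fastq(r2)
  ids1 <- fastq_ids(fq1)
  if (!identical(ids1, fastq_ids(fq2)))
    stop("R1/R2 FASTQ streams are desynchronized")

  if (!is.null(i1) && !is.null(i2)) {
    ix1 <- read_fastq(i1); ix2 <- read_fastq(i2)
    if (!identical(ids1, fastq_ids(ix1)) || !identical(ids1, fastq_ids(ix2)))
      stop("index FASTQ streams are desynchronized with the read streams")
    bc7 <- as.character(ix1)
    bc5 <- as.character(ix2)
  } else {
    # header layout "<id> <read>:<filter>:<control>:<i7>+<i5>"
    comment <- sub("^\\S+\\s*", "", names(fq1))
    bc <- sub("^.*:", "", comment)
    parts <- tstrsplit(bc, "+", fixed = TRUE)
    if (length(parts) != 2L) stop("cannot parse '<i7>+<i5>' barcodes from R1 headers")
    bc7 <- parts[[1]]; bc5 <- parts[[2]]
  }
  L7 <- nchar(sheet$i7[1]); L5 <- nchar(sheet$i5[1])
  bc7 <- substr(bc7, 1L, L7)
  bc5 <- substr(bc5, 1L, L5)

  if (orientation == "auto")
    orientation <- detect_i5_orientation(head(bc5, 10000L), sheet)
  sheet_i5 <- if (orientation == "reverse-complement") revcomp_chr(sheet$i5) else sheet$i5
  msheet <- copy(sheet)[, i5 := sheet_i5]

  hit <- match_barcodes(bc7, bc5, msheet, as.integer(max_mismatch))

  counts <- integer(nrow(sheet))
  for (k in seq_len(nrow(sheet))) {
    sel <- hit == k
    counts[k] <- sum(sel)
    if (counts[k] > 0L) {
      write_fastq(fq1[sel], file.path(out_dir, paste0(sheet$sample_id[k], "_R1.fastq")))
      write_fastq(fq2[sel], file.path(out_dir, paste0(sheet$sample_id[k], "_R2.fastq")))
    }
  }
  und <- hit == 0L
  if (any(und)) {
    write_fastq(fq1[und], file.path(out_dir, "undetermined_R1.fastq"))
    write_fastq(fq2[und], file.path(out_dir, "undetermined_R2.fastq"))
  }

  rep <- structure(list(
    counts = data.table(sample_id = sheet$sample_id, plate_id = sheet$plate_id,
                        is_blank = sheet$is_blank, n_pairs = counts),
    undetermined = sum(und),
    total = length(fq1),
    orientation = orientation,
    out_dir = out_dir
  ), class = "skim_demux_report")
  rep$blanks <- check_blanks(rep)
  stopifnot(sum(rep$counts$n_pairs) + rep$undetermined == rep$total)
  rep
}

#' @export
print.skim_demux_report <- function(x, ...) {
  cat("skim-seq demultiplexing report\n")
  cat("  total read pairs: ", x$total, "\n", sep = "")
  cat("  assigned:         ", sum(x$counts$n_pairs), "\n", sep = "")
  cat("  undetermined:     ", x$undetermined, "\n", sep = "")
  cat("  i5 orientation:   ", x$orientation, "\n", sep = "")
  if (nrow(x$blanks)) {
    cat("  blank wells:\n")
    print(x$blanks)
  }
  invisible(x)
}

#' Blank-well QC
#'
#' A blank well passes when its assigned read pairs are less than
#' `threshold_fraction` (default `1e-4`, i.e. 0.01%) of the mean pairs over
#' non-blank samples.
#'
#' @param report a `skim_demux_report`, or a `data.table` with columns
#'   `sample_id`, `is_blank`, `n_pairs`.
#' @param threshold_fraction pass threshold as a fraction of the non-blank
#'   mean.
#' @return `data.table` with columns `sample_id`, `n_pairs`,
#'   `fraction_of_mean`, `pass` (one row per blank; empty when the sheet has
#'   no blanks).
#' @export
check_blanks <- function(report, threshold_fraction = 1e-4) {
  counts <- if (inherits(report, "skim_demux_report")) report$counts
            else as.data.table(report)
  if (!any(!counts$is_blank)) stop("no non-blank samples to form a baseline")
  mu <- mean(counts$n_pairs[!counts$is_blank])
  bl <- counts[is_blank == TRUE,
               .(sample_id, n_pairs, fraction_of_mean = n_pairs / mu)]
  bl[, pass := fraction_of_mean < threshold_fraction]
  bl[]
}
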