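#' Genome catalogs and hybrid references
#'
#' A genome catalog is the coordinate frame for all downstream analysis: a
#' table of contigs with their lengths, a label for the source genome each
#' contig came from, and the contig's name in the original assembly. For
#' interspecific introgression mapping two assemblies are concatenated into an
#' "in silico hybrid" reference so that reads partition between the recipient
#' and donor genomes by best alignment.
#'
#' @name catalog
NULL

#' Construct a genome catalog
#'
#' @param contig_id character vector of unique contig names.
#' @param length_bp positive integer vector of contig lengths.
#' @param source_genome label of the source assembly per contig (recycled).
#' @param original_id contig name in the source assembly; defaults to
#'   `contig_id`.
#' @return A `data.table` of class `genome_catalog` with columns
#'   `contig_id`, `source_genome`, `original_id`, `length_bp`.
#' @export
genome_catalog <- function(contig_id, length_bp, source_genome = "genome",
                           original_id = contig_id) {
  cat <- data.table(
    contig_id = as.character(contig_id),
    source_genome = as.character(source_genome),
    original_id = as.character(original_id),
    length_bp = as.numeric(length_bp)
  )
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  cat <- as.data.table(cat)
  need <- c("contig_id", "source_genome", "original_id", "length_bp")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cat$contig_id))
    stop("duplicate contig_id in catalog: ",
         paste(unique(cat$contig_id[duplicated(cat$contig_id)]), collapse = ", "))
  if (any(!is.finite(cat$length_bp)) || any(cat$length_bp <= 0))
    stop("every catalog length_bp must be a positive number")
  setattr(cat, "class", c("genome_catalog", class(data.table())))
  cat[]
}

#' Build a catalog by scanning a FASTA file
#'
#' Contig lengths are computed from the sequences; `source_genome` is a single
#' label applied to every contig.
#'
#' @param fasta path to a FASTA file.
#' @param label source-genome label.
#' @return A [genome_catalog()].
#' @export
catalog_from_fasta <- function(fasta, label = "genome") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("FASTA contains no sequences: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  genome_catalog(ids, Biostrings::width(seqs), label)
}

#' Concatenate two assemblies into a hybrid reference
#'
#' Writes a FASTA that is the recipient assembly followed by the donor
#' assembly, with every header rewritten to `<label>_<original_id>` so that
#' contig names are unique even when both assemblies use the same chromosome
#' names. A catalog recording length, source genome and original name per
#' contig is returned and (optionally) written as a TSV sidecar so external
#' aligner output can be interpreted.
#'
#' @param fasta_recipient,fasta_donor paths to the two input FASTA files.
#' @param label_recipient,label_donor distinct source-genome labels.
#' @param out_fasta output path for the hybrid FASTA.
#' @param out_catalog optional output path for the catalog TSV sidecar.
#' @return list with `fasta` (path) and `catalog` ([genome_catalog()]).
#' @export
build_hybrid_reference <- function(fasta_recipient, fasta_donor,
                                   label_recipient, label_donor,
                                   out_fasta,
                                   out_catalog = paste0(out_fasta, ".catalog.tsv")) {
  if (identical(label_recipient, label_donor))
    stop("recipient and donor labels must differ")
  rec <- Biostrings::readDNAStringSet(fasta_recipient)
  don <- Biostrings::readDNAStringSet(fasta_donor)
  if (length(rec) == 0L) stop("recipient FASTA contains no sequences")
  if (length(don) == 0L) stop("donor FASTA contains no sequences")
  rec_ids <- sub("\\s.*$", "", names(rec))
  don_ids <- sub("\\s.*$", "", names(don))
  new_ids <- c(paste0(label_recipient, "_", rec_ids),
               paste0(label_donor, "_", don_ids))
  if (anyDuplicated(new_ids))
    stop("duplicate contig id after renaming: ",
         paste(unique(new_ids[duplicated(new_ids)]), collapse = ", "))
  hyb <- c(rec, don)
  names(hyb) <- new_ids
  Biostrings::writeXStringSet(hyb, out_fasta)
  cat <- genome_catalog(
    contig_id = new_ids,
    length_bp = Biostrings::width(hyb),
    source_genome = rep(c(label_recipient, label_donor),
                        c(length(rec), length(don))),
    original_id = c(rec_ids, don_ids)
  )
  if (!is.null(out_catalog)) write_catalog(cat, out_catalog)
  list(fasta = out_fasta, catalog = cat)
}

#' Read / write a catalog TSV
#'
#' The sidecar format is tab-delimited with header
#' `contig_id  source_genome  original_id  length_bp`.
#'
#' @param path file path.
#' @return [read_catalog()] returns a [genome_catalog()];
#'   [write_catalog()] returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  cat <- fread(path, sep = "\t")
  validate_catalog(cat)
}

#' @param cat a [genome_catalog()].
#' @rdname read_catalog
#' @export
write_catalog <- function(cat, path) {
  validate_catalog(cat)
  fwrite(cat[, .(contig_id, source_genome, original_id, length_bp)],
         path, sep = "\t")
  invisible(path)
}

#' Read a catalog from FASTA or TSV, by extension
#' @inheritParams read_catalog
#' @param label source label when reading FASTA.
#' @export
load_catalog <- function(path, label = "genome") {
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
    catalog_from_fasta(path, label)
  else read_catalog(path)
}

#' Centromere positions
#'
#' Centromeres split chromosomes into a short arm (`[0, centromere)`) and a
#' long arm (`[centromere, length)`) for arm-level dosage calls and karyogram
#' annotation. Accepted formats: 2-column TSV (`contig_id`, `centromere_bp`)
#' or 3-column BED (`contig`, `centromere_bp - 1`, `centromere_bp`).
#'
#' @param path file path.
#' @param catalog optional [genome_catalog()] to validate against.
#' @return `data.table` with columns `contig_id`, `centromere_bp`.
#' @export
read_centromeres <- function(path, catalog = NULL) {
  x <- fread(path, header = FALSE, sep = "\t")
  if (ncol(x) >= 3L && is.numeric(x[[2]]) && is.numeric(x[[3]])) {
    cen <- data.table(contig_id = as.character(x[[1]]),
                      centromere_bp = as.numeric(x[[3]]))
  } else {
    cen <- data.table(contig_id = as.character(x[[1]]),
                      centromere_bp = as.numeric(x[[2]]))
  }
  validate_centromeres(cen, catalog)
}

validate_centromeres <- function(cen, catalog = NULL) {
  cen <- as.data.table(cen)
  if (!all(c("contig_id", "centromere_bp") %in% names(cen)))
    stop("centromere map needs columns contig_id, centromere_bp")
  if (!is.null(catalog)) {
    catalog <- validate_catalog(catalog)
    miss <- setdiff(cen$contig_id, catalog$contig_id)
    if (length(miss))
      stop("centromere contigs absent from catalog: ",
           paste(miss, collapse = ", "))
    len <- catalog$length_bp[match(cen$contig_id, catalog$contig_id)]
    bad <- cen$centromere_bp <= 0 | cen$centromere_bp >= len
    if (any(bad))
      stop("centromere position outside (0, length) for: ",
           paste(cen$contig_id[bad], collapse = ", "))
  } else if (any(cen$centromere_bp <= 0)) {
    stop("centromere positions must be positive")
  }
  cen[]
}

#' @param cen centromere table as returned by [read_centromeres()].
#' @param format `"tsv"` (2 columns) or `"bed"` (3 columns, 0-based).
#' @rdname read_centromeres
#' @export
write_centromeres <- function(cen, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  cen <- validate_centromeres(cen)
  out <- if (format == "bed")
    data.table(cen$contig_id, cen$centromere_bp - 1, cen$centromere_bp)
  else data.table(cen$contig_id, cen$centromere_bp)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
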