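#' Parental SNP discovery and sparse progeny genotyping
#'
#' Doubled-haploid (DH) progeny of a biparental cross are mosaics of the two
#' parental haplotypes, so genotyping reduces to deciding, at sites where the
#' parents differ, which parent each read supports. Parental SNPs are
#' discovered from moderate-coverage parental pileups with depth filters
#' (per-parent depth in [6, 100], each parent's allele supported by at least
#' 3 reads) and a major-allele purity rule standing in for a homozygosity
#' call. Progeny at 0.01-0.1x coverage see at most a read or two per site, so
#' a single read is accepted as evidence for its parent; heterozygous calls
#' in a DH are retained only as a contamination/error signal. Parental
#' haplotype blocks are then assigned by majority vote in non-overlapping
#' windows and merged, which localizes recombination breakpoints to a few Mb
#' even at 95-99% missing data.
#'
#' @name genotyping
NULL

BASES <- c("A", "C", "G", "T")

#' Read an allele-depth pileup table
#'
#' Tab-delimited with header `chrom  pos  ref  A  C  G  T` (per-base read
#' depths after filtering).
#'
#' @param path TSV path.
#' @return `data.table` with those columns plus `DP` (total depth).
#' @export
read_pileup <- function(path) {
  x <- fread(path, sep = "\t")
  need <- c("chrom", "pos", "ref", BASES)
  if (!all(need %in% names(x)))
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  x[, DP := A + C + G + T]
  x[]
}

major_allele <- function(x) {
  d <- as.matrix(x[, BASES, with = FALSE])
  i <- max.col(d, ties.method = "first")
  list(base = BASES[i],
       depth = d[cbind(seq_len(nrow(d)), i)])
}

#' Discover homozygous SNP differences between two parents
#'
#' A site is kept when each parent's filtered depth is within
#' `[min_dp, max_dp]`, each parent's major-allele fraction is at least
#' `min_purity` (homozygosity proxy), the two major alleles differ, and each
#' parent's own allele is supported by at least `min_allele_depth` reads.
#'
#' @param pileup_a,pileup_b parental pileups ([read_pileup()] format), on a
#'   shared coordinate frame; only sites present in both are considered.
#' @param min_dp,max_dp per-parent depth bounds (defaults 6 and 100).
#' @param min_allele_depth minimum reads supporting each parent's allele
#'   (default 3).
#' @param min_purity minimum major-allele fraction per parent (default 0.9).
#' @return `data.table` of class `parental_variants` with columns `chrom`,
#'   `pos`, `ref`, `allele_A`, `allele_B`, `dp_A`, `dp_B`, `ad_A`, `ad_B`;
#'   `attr(., "n_candidate")` is the number of shared sites examined.
#' @export
discover_parental_snps <- function(pileup_a, pileup_b, min_dp = 6,
                                   max_dp = 100, min_allele_depth = 3,
                                   min_purity = 0.9) {
  a <- as.data.table(pileup_a); b <- as.data.table(pileup_b)
  if (!"DP" %in% names(a)) a[, DP := A + C + G + T]
  if (!"DP" %in% names(b)) b[, DP := A + C + G + T]
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c("_a", "_b"))
  n_candidate <- nrow(m)
  if (!n_candidate) {
    out <- data.table(chrom = character(0), pos = numeric(0), ref = character(0),
                      allele_A = character(0), allele_B = character(0),
                      dp_A = numeric(0), dp_B = numeric(0),
                      ad_A = numeric(0), ad_B = numeric(0))
    setattr(out, "n_candidate", 0L)
    return(out)
  }
  ma <- major_allele(setnames(m[, paste0(BASES, "_a"), with = FALSE], BASES))
  mb <- major_allele(setnames(m[, paste0(BASES, "_b"), with = FALSE], BASES))
  keep <- m$DP_a >= min_dp & m$DP_a <= max_dp &
          m$DP_b >= min_dp & m$DP_b <= max_dp &
          ma$depth / m$DP_a >= min_purity &
          mb$depth / m$DP_b >= min_purity &
          ma$base != mb$base &
          ma$depth >= min_allele_depth & mb$depth >= min_allele_depth
  ref_col <- if ("ref_a" %in% names(m)) m$ref_a else m$ref
  out <- data.table(chrom = m$chrom, pos = m$pos, ref = ref_col,
                    allele_A = ma$base, allele_B = mb$base,
                    dp_A = m$DP_a, dp_B = m$DP_b,
                    ad_A = ma$depth, ad_B = mb$depth)[keep]
  setorder(out, chrom, pos)
  setattr(out, "n_candidate", n_candidate)
  setattr(out, "class", c("parental_variants", class(data.table())))
  out[]
}

#' Genotype a low-coverage sample at parental SNP sites
#'
#' Counts reads supporting each parent's allele at each variant site:
#' call `A` when only A-allele reads are seen, `B` when only B-allele reads,
#' `het` when both, `missing` when neither. Reads carrying a third allele are
#' ignored (tallied in `attr(., "n_third_allele")`).
#'
#' @param pileup sample pileup ([read_pileup()] format); sites absent from
#'   the pileup are `missing`.
#' @param variants a `parental_variants` table.
#' @param sample_id sample name for the output.
#' @return `data.table` with `sample`, `chrom`, `pos`, `call`, `n_A`, `n_B`.
#' @export
genotype_at_sites <- function(pileup, variants, sample_id = "sample") {
  stopifnot(nrow(variants) > 0)
  v <- as.data.table(variants)[, .(chrom, pos, allele_A, allele_B)]
  p <- as.data.table(pileup)
  m <- merge(v, p, by = c("chrom", "pos"), all.x = TRUE)
  d <- as.matrix(m[, BASES, with = FALSE])
  d[is.na(d)] <- 0
  idxA <- match(m$allele_A, BASES)
  idxB <- match(m$allele_B, BASES)
  nA <- d[cbind(seq_len(nrow(d)), idxA)]
  nB <- d[cbind(seq_len(nrow(d)), idxB)]
  third <- rowSums(d) - nA - nB
  out <- data.table(sample = sample_id, chrom = m$chrom, pos = m$pos,
                    call = fifelse(nA > 0 & nB > 0, "het",
                            fifelse(nA > 0, "A",
                             fifelse(nB > 0, "B", "missing"))),
                    n_A = nA, n_B = nB)
  setorder(out, chrom, pos)
  setattr(out, "n_third_allele", sum(third))
  out[]
}

#' Per-sample missingness and marker counts
#'
#' @param calls genotype calls (one or more samples) from
#'   [genotype_at_sites()] or [simulate_dh_population()].
#' @return list with `per_sample` (`sample`, `n_sites`, `n_genotyped`,
#'   `fraction_missing`) and `n_sites_genotyped_population` (unique sites
#'   genotyped in at least one sample).
#' @export
missingness_profile <- function(calls) {
  calls <- as.data.table(calls)
  per_sample <- calls[, .(
    n_sites = .N,
    n_genotyped = sum(call != "missing"),
    fraction_missing = mean(call == "missing")), by = sample]
  pop <- calls[call != "missing", uniqueN(paste(chrom, pos))]
  list(per_sample = per_sample[], n_sites_genotyped_population = pop)
}

#' Assign parental haplotype blocks from sparse calls
#'
#' Non-overlapping windows of `window_bp` are assigned to a parent when they
#' hold at least `min_markers` informative (A or B) calls and the majority
#' parent reaches the `majority` fraction; otherwise they are `unresolved`.
#' An unresolved run flanked by the same resolved parent on both sides (or
#' on its only side, at a chromosome end) is absorbed into that parent's
#' block; runs between discordant parents stay unresolved.
#' Adjacent windows with the same assignment merge into blocks; the boundary
#' between two blocks of different parents is placed midway between the last
#' informative marker of the left block and the first of the right.
#'
#' @param calls genotype calls for one sample, sorted by position.
#' @param window_bp window width (default 5 Mb).
#' @param min_markers minimum informative calls per window (default 3).
#' @param majority majority-vote fraction (default 0.8).
#' @return `data.table` with `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `parent` (`A`/`B`/`unresolved`), `n_markers`, `fraction_concordant`.
#' @export
call_haplotype_blocks <- function(calls, window_bp = 5e6, min_markers = 3L,
                                  majority = 0.8) {
  calls <- as.data.table(calls)
  if (!"sample" %in% names(calls)) calls[, sample := "sample"]
  out <- calls[, call_blocks_one(.SD, window_bp, min_markers, majority),
               by = .(sample, chrom)]
  out[]
}

call_blocks_one <- function(d, window_bp, min_markers, majority) {
  inf <- d[call %in% c("A", "B")]
  if (!nrow(inf)) return(NULL)
  setorder(inf, pos)
  inf[, window := floor(pos / window_bp)]
  w <- inf[, .(
    n_A = sum(call == "A"), n_B = sum(call == "B"),
    first_pos = min(pos), last_pos = max(pos)), by = window]
  setorder(w, window)
  w[, n_inf := n_A + n_B]
  w[, frac := pmax(n_A, n_B) / n_inf]
  w[, parent := fifelse(n_inf >= min_markers & frac >= majority,
                        fifelse(n_A >= n_B, "A", "B"), "unresolved")]
  # an unresolved run flanked by the same resolved parent (or with a single
  # resolved neighbour at a chromosome end) belongs to that parent's block
  res_idx <- which(w$parent != "unresolved")
  if (length(res_idx)) {
    for (i in which(w$parent == "unresolved")) {
      left <- res_idx[res_idx < i]
      right <- res_idx[res_idx > i]
      lp <- if (length(left)) w$parent[max(left)] else NA_character_
      rp <- if (length(right)) w$parent[min(right)] else NA_character_
      if (is.na(lp) && !is.na(rp)) w$parent[i] <- rp
      else if (!is.na(lp) && is.na(rp)) w$parent[i] <- lp
      else if (!is.na(lp) && identical(lp, rp)) w$parent[i] <- lp
    }
  }
  # merge consecutive windows with identical assignment
  w[, seg := rleid(parent)]
  blocks <- w[, .(
    parent = parent[1],
    first_pos = min(first_pos), last_pos = max(last_pos),
    n_markers = sum(n_inf),
    fraction_concordant = {
      conc <- if (parent[1] == "A") sum(n_A)
              else if (parent[1] == "B") sum(n_B)
              else sum(pmax(n_A, n_B))
      conc / sum(n_inf)
    }), by = seg]
  n <- nrow(blocks)
  start_bp <- blocks$first_pos
  end_bp <- blocks$last_pos
  if (n > 1L) {
    mid <- (blocks$last_pos[-n] + blocks$first_pos[-1]) / 2
    end_bp[-n] <- mid
    start_bp[-1] <- mid
  }
  data.table(start_bp = start_bp, end_bp = end_bp, parent = blocks$parent,
             n_markers = blocks$n_markers,
             fraction_concordant = blocks$fraction_concordant)
}

#' Write a genotype matrix TSV (sites x samples, coded A/B/H/N)
#' @param calls calls for a population.
#' @param path output path.
#' @export
write_genotype_matrix <- function(calls, path) {
  calls <- as.data.table(calls)
  code <- c(A = "A", B = "B", het = "H", missing = "N")
  calls[, value := code[call]]
  wide <- dcast(calls, chrom + pos ~ sample, value.var = "value",
                fill = "N")
  fwrite(wide, path, sep = "\t")
  invisible(path)
}
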