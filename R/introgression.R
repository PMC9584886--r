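#' Segmentation, translocation pairing and segregation tests
#'
#' On a hybrid reference an interspecific translocation shows up as paired
#' signals: a run of recipient bins dropping to ~0 (homozygous) or ~0.5
#' (heterozygous) copy ratio, and a run of donor bins rising from ~0 to ~1
#' (homozygous two-copy gain relative to the recipient disomic level is ratio
#' 1) or ~0.5 (one copy). Copy-ratio tracks are segmented by mean-shift
#' binary segmentation -- the track is recursively split at the bin that
#' minimizes the within-segment sum of squares, a split being accepted when
#' its mean-difference z-score reaches `z_threshold` and both sides have at
#' least `min_seg_bins` bins. The noise scale entering the z-score is
#' estimated within each candidate segment as the median absolute deviation
#' of lag-1 bin differences divided by sqrt(2), which is robust to the
#' copy-number steps themselves (with a plain-sd fallback when runs of
#' identical values degenerate the MAD). Recipient losses are then paired with donor
#' gains of matching dosage to call zygosity, and carrier counts are tested
#' against 1:1 segregation with a 1-df Pearson chi-square.
#'
#' @name introgression
NULL

# Noise scale of a piecewise-constant segment, from lag-1 differences: the
# few diffs that straddle changepoints do not move the median, so the MAD
# is not inflated by the signal. When more than half the diffs are ties
# (e.g. runs of exactly-zero bins) the MAD degenerates to 0; fall back to
# the plain sd of the diffs, which over-counts the steps but stays > 0.
segment_noise_sd <- function(seg) {
  if (length(seg) < 3L) return(0)
  dd <- diff(seg)
  s <- stats::mad(dd) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- stats::sd(dd) / sqrt(2)
  if (!is.finite(s)) 0 else s
}

# recursive mean-shift binary segmentation over x[lo..hi]; returns split
# points as indices of the first element of the right-hand segment.
# `floor_sd` (the whole-track noise scale) guards against chance
# under-estimation of the noise on short sub-segments.
bseg_recurse <- function(x, lo, hi, min_seg_bins, z_threshold, floor_sd = 0) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg_bins) return(integer(0))
  seg <- x[lo:hi]
  noise_sd <- max(segment_noise_sd(seg), floor_sd)
  cs <- cumsum(seg)
  cs2 <- cumsum(seg^2)
  k <- min_seg_bins:(n - min_seg_bins)
  mL <- cs[k] / k
  mR <- (cs[n] - cs[k]) / (n - k)
  ss <- (cs2[k] - k * mL^2) + (cs2[n] - cs2[k] - (n - k) * mR^2)
  i <- which.min(ss)
  kb <- k[i]
  dm <- abs(mL[i] - mR[i])
  z <- if (noise_sd > 0) dm / (noise_sd * sqrt(1 / kb + 1 / (n - kb)))
       else if (dm > 0) Inf else 0
  if (z < z_threshold) return(integer(0))
  cut <- lo + kb  # first index of right segment (absolute)
  c(bseg_recurse(x, lo, cut - 1L, min_seg_bins, z_threshold, floor_sd),
    cut,
    bseg_recurse(x, cut, hi, min_seg_bins, z_threshold, floor_sd))
}

# Post-pass on the recursive splits: the first cut of a multi-step track is
# a least-squares compromise between the true boundaries, and min_seg_bins
# can block the recursion from correcting it by one or two bins. Each cut is
# repositioned to the unconstrained SS optimum between its neighbours, and
# cuts whose local z-score no longer clears the threshold are pruned.
refine_cuts <- function(x, cuts, z_threshold, floor_sd, max_iter = 5L) {
  n <- length(x)
  if (!length(cuts)) return(cuts)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    cuts <- sort(unique(cuts))
    for (j in seq_along(cuts)) {
      lo <- if (j == 1L) 1L else cuts[j - 1L]
      hi <- if (j == length(cuts)) n else cuts[j + 1L] - 1L
      seg <- x[lo:hi]
      m <- length(seg)
      if (m < 2L) next
      cs <- cumsum(seg); cs2 <- cumsum(seg^2)
      k <- 1:(m - 1L)
      mL <- cs[k] / k
      mR <- (cs[m] - cs[k]) / (m - k)
      ss <- (cs2[k] - k * mL^2) + (cs2[m] - cs2[k] - (m - k) * mR^2)
      newcut <- lo + k[which.min(ss)]
      if (newcut != cuts[j]) { cuts[j] <- newcut; changed <- TRUE }
    }
    repeat {
      cuts <- sort(unique(cuts))
      if (!length(cuts)) break
      zs <- vapply(seq_along(cuts), function(j) {
        lo <- if (j == 1L) 1L else cuts[j - 1L]
        hi <- if (j == length(cuts)) n else cuts[j + 1L] - 1L
        kb <- cuts[j] - lo
        m <- hi - lo + 1L
        if (kb < 1L || kb >= m) return(0)
        seg <- x[lo:hi]
        s <- max(segment_noise_sd(seg), floor_sd)
        dm <- abs(mean(seg[1:kb]) - mean(seg[(kb + 1L):m]))
        if (s > 0) dm / (s * sqrt(1 / kb + 1 / (m - kb)))
        else if (dm > 0) Inf else 0
      }, numeric(1))
      if (all(zs >= z_threshold)) break
      cuts <- cuts[-which.min(zs)]
      changed <- TRUE
    }
    if (!changed) break
  }
  cuts
}

state_from_ratio <- function(mean_ratio) {
  cp <- copies_from_ratio(mean_ratio)
  fcase(cp == 0L, "absent",
        cp == 1L, "hemizygous",
        cp == 2L, "normal",
        default = "gain")
}

#' Segment one contig's copy-ratio track
#'
#' Masked bins (`NA` ratio) are excluded from segmentation; segment
#' boundaries in bp follow the retained bins. Segment state comes from the
#' rounded copy number of the segment mean ratio: `absent` (0 copies),
#' `hemizygous` (1), `normal` (2), `gain` (>2).
#'
#' @param ratio numeric vector of bin copy ratios, in genomic order.
#' @param start,end bin coordinates (0-based half-open), same length.
#' @param min_seg_bins minimum bins per segment (default 3).
#' @param z_threshold acceptance z-score for a split (default 4).
#' @return `data.table` of segments (`start_bp`, `end_bp`, `n_bins`,
#'   `mean_ratio`, `state`) with the changepoint indices (positions in the
#'   unmasked track) in `attr(result, "changepoints")`.
#' @export
segment_bins <- function(ratio, start, end, min_seg_bins = 3L,
                         z_threshold = 4) {
  stopifnot(length(ratio) == length(start), length(start) == length(end),
            min_seg_bins >= 1L)
  keep <- !is.na(ratio)
  if (!any(keep)) {
    out <- data.table(start_bp = numeric(0), end_bp = numeric(0),
                      n_bins = integer(0), mean_ratio = numeric(0),
                      state = character(0))
    setattr(out, "changepoints", integer(0))
    return(out)
  }
  x <- ratio[keep]; s <- start[keep]; e <- end[keep]
  o <- order(s); x <- x[o]; s <- s[o]; e <- e[o]
  floor_sd <- segment_noise_sd(x)
  cuts <- bseg_recurse(x, 1L, length(x), as.integer(min_seg_bins), z_threshold,
                       floor_sd = floor_sd)
  cuts <- refine_cuts(x, cuts, z_threshold, floor_sd)
  bounds <- c(1L, cuts, length(x) + 1L)
  segs <- lapply(seq_len(length(bounds) - 1L), function(j) {
    i0 <- bounds[j]; i1 <- bounds[j + 1L] - 1L
    data.table(start_bp = s[i0], end_bp = e[i1], n_bins = i1 - i0 + 1L,
               mean_ratio = mean(x[i0:i1]))
  })
  out <- rbindlist(segs)
  out[, state := state_from_ratio(mean_ratio)]
  setattr(out, "changepoints", cuts)
  out[]
}

#' Segment every contig of every sample in a profile
#'
#' @param profile a `dosage_profile` from [compute_copy_ratio()].
#' @param mask optional `data.table` (`chrom`, `start`, `end`) of bins to
#'   exclude (known reference artifacts); bins overlapping a mask interval
#'   are set `NA` before segmentation.
#' @inheritParams segment_bins
#' @return `data.table` of segments with `sample` and `chrom` columns.
#' @export
segment_profile <- function(profile, mask = NULL, min_seg_bins = 3L,
                            z_threshold = 4) {
  stopifnot(inherits(profile, "dosage_profile"))
  bins <- copy(profile$bins)
  if (!is.null(mask)) {
    mask <- as.data.table(mask)
    for (j in seq_len(nrow(mask)))
      bins[chrom == mask$chrom[j] & start < mask$end[j] & end > mask$start[j],
           ratio := NA_real_]
  }
  bins[, {
    sg <- segment_bins(ratio, start, end, min_seg_bins, z_threshold)
    if (nrow(sg)) sg else NULL
  }, by = .(sample, chrom)]
}

#' Pair recipient losses with donor gains into translocation calls
#'
#' Recipient segments with state `absent` or `hemizygous` and length at
#' least `min_mb` are paired with donor segments of the matching dosage
#' class: a two-copy donor gain (state `normal`, ratio ~1) with a recipient
#' `absent` segment gives a homozygous translocation; a one-copy donor gain
#' (state `hemizygous`, ratio ~0.5) with a recipient `hemizygous` segment
#' gives a heterozygous one. When several candidates match, the pair with
#' the closest segment lengths wins. Unpaired recipient losses are reported
#' as deletions and unpaired donor gains as additions.
#'
#' @param segments segment table from [segment_profile()] (one or more
#'   samples).
#' @param catalog hybrid [genome_catalog()].
#' @param recipient_label,donor_label source-genome labels.
#' @param min_mb minimum reportable segment length in Mb (default 3).
#' @return `data.table` with one row per event: `type`
#'   (`translocation`/`deletion`/`addition`), recipient and donor intervals,
#'   `zygosity`, `recipient_loss_mb`, `donor_gain_mb`, `designation`.
#' @export
pair_translocations <- function(segments, catalog, recipient_label,
                                donor_label, min_mb = 3) {
  catalog <- validate_catalog(catalog)
  rec_contigs <- catalog[source_genome == recipient_label, contig_id]
  don_contigs <- catalog[source_genome == donor_label, contig_id]
  segs <- as.data.table(segments)
  if (!"sample" %in% names(segs)) segs[, sample := "sample"]
  min_bp <- min_mb * 1e6

  out <- list()
  for (s in unique(segs$sample)) {
    ss <- segs[sample == s]
    loss <- ss[chrom %in% rec_contigs & state %in% c("absent", "hemizygous") &
               end_bp - start_bp >= min_bp]
    gain <- ss[chrom %in% don_contigs & state != "absent" &
               end_bp - start_bp >= min_bp]
    gain_used <- rep(FALSE, nrow(gain))
    loss_used <- rep(FALSE, nrow(loss))
    for (j in seq_len(nrow(loss))) {
      want_state <- if (loss$state[j] == "absent") "normal" else "hemizygous"
      cand <- which(!gain_used & gain$state == want_state)
      if (!length(cand)) next
      llen <- loss$end_bp[j] - loss$start_bp[j]
      pick <- cand[which.min(abs((gain$end_bp[cand] - gain$start_bp[cand]) - llen))]
      gain_used[pick] <- TRUE
      loss_used[j] <- TRUE
      zyg <- if (loss$state[j] == "absent") "homozygous" else "heterozygous"
      out[[length(out) + 1L]] <- data.table(
        sample = s, type = "translocation",
        recipient_contig = loss$chrom[j],
        recipient_start_bp = loss$start_bp[j], recipient_end_bp = loss$end_bp[j],
        donor_contig = gain$chrom[pick],
        donor_start_bp = gain$start_bp[pick], donor_end_bp = gain$end_bp[pick],
        zygosity = zyg,
        recipient_loss_mb = llen / 1e6,
        donor_gain_mb = (gain$end_bp[pick] - gain$start_bp[pick]) / 1e6
      )
    }
    if (any(!loss_used))
      out[[length(out) + 1L]] <- loss[!loss_used][, .(
        sample = s, type = "deletion", recipient_contig = chrom,
        recipient_start_bp = start_bp, recipient_end_bp = end_bp,
        donor_contig = NA_character_, donor_start_bp = NA_real_,
        donor_end_bp = NA_real_,
        zygosity = fifelse(state == "absent", "homozygous", "heterozygous"),
        recipient_loss_mb = (end_bp - start_bp) / 1e6,
        donor_gain_mb = NA_real_)]
    if (any(!gain_used))
      out[[length(out) + 1L]] <- gain[!gain_used][, .(
        sample = s, type = "addition", recipient_contig = NA_character_,
        recipient_start_bp = NA_real_, recipient_end_bp = NA_real_,
        donor_contig = chrom, donor_start_bp = start_bp, donor_end_bp = end_bp,
        zygosity = fifelse(state == "normal", "homozygous",
                    fifelse(state == "hemizygous", "heterozygous", "gain")),
        recipient_loss_mb = NA_real_,
        donor_gain_mb = (end_bp - start_bp) / 1e6)]
  }
  if (!length(out)) {
    return(data.table(sample = character(0), type = character(0),
                      recipient_contig = character(0),
                      recipient_start_bp = numeric(0), recipient_end_bp = numeric(0),
                      donor_contig = character(0), donor_start_bp = numeric(0),
                      donor_end_bp = numeric(0), zygosity = character(0),
                      recipient_loss_mb = numeric(0), donor_gain_mb = numeric(0),
                      designation = character(0), pair = character(0)))
  }
  res <- rbindlist(out, use.names = TRUE)
  res[, designation := fifelse(type == "translocation",
    paste0(recipient_contig, ":", round(recipient_start_bp / 1e6), "-",
           round(recipient_end_bp / 1e6), "Mb<-", donor_contig, ":",
           round(donor_start_bp / 1e6), "-", round(donor_end_bp / 1e6), "Mb"),
    NA_character_)]
  # contig-level pairing id: the grouping unit for population summaries,
  # insensitive to bin-level breakpoint scatter between samples
  res[, pair := fifelse(type == "translocation",
                        paste0(recipient_contig, "<-", donor_contig),
                        NA_character_)]
  setorder(res, sample, type)
  res[]
}

#' 1:1 segregation chi-square test
#'
#' Pearson goodness-of-fit of carrier vs non-carrier counts against the
#' 1:1 ratio expected for a single heterozygous introgression in a BC1,
#' with 1 degree of freedom.
#'
#' @param n_carrier,n_noncarrier observed counts.
#' @return list with `chi_square`, `df`, `p_value`, `n`.
#' @export
segregation_test <- function(n_carrier, n_noncarrier) {
  n <- n_carrier + n_noncarrier
  stopifnot(n > 0)
  e <- n / 2
  chi <- (n_carrier - e)^2 / e + (n_noncarrier - e)^2 / e
  list(chi_square = chi, df = 1L,
       p_value = pchisq(chi, df = 1, lower.tail = FALSE), n = n)
}

#' Summarize carriers per designation and test segregation
#'
#' @param calls translocation calls from [pair_translocations()] (population
#'   of samples).
#' @param all_samples character vector of every genotyped sample (so
#'   non-carriers are counted); defaults to the samples present in `calls`.
#' @param by column to group designations by (default `"designation"`).
#' @return `data.table` with per-designation carrier / non-carrier counts,
#'   chi-square and p-value.
#' @export
summarize_population <- function(calls, all_samples = NULL,
                                 by = "designation") {
  calls <- as.data.table(calls)
  if (is.null(all_samples)) all_samples <- unique(calls$sample)
  n_total <- length(all_samples)
  tr <- calls[type == "translocation"]
  if (!nrow(tr))
    return(data.table(designation = character(0), n_carrier = integer(0),
                      n_noncarrier = integer(0), chi_square = numeric(0),
                      p_value = numeric(0)))
  tr[, designation := get(by)]
  smry <- tr[, .(n_carrier = uniqueN(sample)), by = designation]
  smry[, n_noncarrier := n_total - n_carrier]
  smry[, c("chi_square", "p_value") := {
    st <- segregation_test(n_carrier, n_noncarrier)
    .(st$chi_square, st$p_value)
  }, by = designation]
  smry[]
}

#' Read a BED mask of bins to exclude from segmentation
#' @param path 3-column BED (chrom, start, end; 0-based half-open).
#' @return `data.table` with `chrom`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t")
  setnames(x, 1:3, c("chrom", "start", "end"))
  x[, .(chrom = as.character(chrom), start = as.numeric(start),
        end = as.numeric(end))]
}
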