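#' Copy-ratio profiles and dosage classification
#'
#' Binned, normalized read counts are converted into copy ratios (observed
#' density over the expected disomic baseline; ~1 for two copies, ~0.5 for
#' one, ~0 for none) and then into whole-chromosome and arm-level dosage
#' classes: disomic, monosomic, nullisomic, trisomic, telosomic (a single
#' chromosome arm), or a monosome plus a telosome.
#'
#' Two baselines are available. The population baseline takes the per-bin
#' median across samples, which absorbs bin-specific biases but is only valid
#' when fewer than half the samples share a dosage event on that chromosome.
#' The self baseline takes the sample's own genome-wide median bin count
#' (valid when most of that genome is disomic). `baseline = "auto"` uses the
#' population baseline but falls back to the self baseline for any contig
#' whose population-median density deviates more than 20% from the genome-wide
#' level -- the situation of a monosomic-parent panel where most progeny are
#' monosomic for the same chromosome, making the population median itself
#' aberrant there.
#'
#' @name karyotype
NULL

#' Compute copy ratios from normalized bin counts
#'
#' @param x a normalized `bin_counts` table (see [normalize_bin_counts()]).
#' @param baseline `"auto"`, `"population_median"` or `"self_genome_median"`.
#' @param deviation_threshold for `"auto"`: relative deviation of a contig's
#'   population-median density from the genome-wide level beyond which the
#'   self baseline is used for that contig (default 0.2).
#' @param exclude_samples samples (blanks, failed) excluded from the
#'   population baseline; their ratios are still computed.
#' @return a `dosage_profile`: list with `bins` (per-bin `ratio`, `baseline`
#'   used) and `contigs` (per sample x contig `mean_ratio`, `n_bins`).
#' @export
compute_copy_ratio <- function(x,
                               baseline = c("auto", "population_median",
                                            "self_genome_median"),
                               deviation_threshold = 0.2,
                               exclude_samples = character(0)) {
  baseline <- match.arg(baseline)
  b <- as.data.table(x)[, .(sample, chrom, start, end, norm)]
  if (all(is.na(b$norm))) stop("normalize the counts first (norm is all NA)")
  bin_size <- attr(x, "bin_size") %||% max(b$end - b$start)
  b[, width := (end - start) / bin_size]

  n_samples <- uniqueN(b$sample)
  if (baseline == "population_median" && n_samples < 3L)
    stop("population_median baseline needs at least 3 samples")

  # self baseline: per-sample disomic level per unit bin width
  b[, level := norm / width]
  self_med <- b[, .(self = median(level)), by = sample]
  b <- merge(b, self_med, by = "sample")
  b[, ratio_self := ifelse(self > 0, level / self, NA_real_)]

  if (baseline == "self_genome_median" || n_samples < 3L) {
    b[, `:=`(ratio = ratio_self, baseline = "self")]
  } else {
    base_pool <- b[!(sample %in% exclude_samples)]
    popmed <- base_pool[, .(popmed = median(norm)), by = .(chrom, start)]
    b <- merge(b, popmed, by = c("chrom", "start"), all.x = TRUE)
    b[, ratio_pop := ifelse(!is.na(popmed) & popmed > 0, norm / popmed, NA_real_)]
    # rescale so each sample's genome-wide median population-ratio is 1
    b[, ratio_pop := {
      m <- median(ratio_pop, na.rm = TRUE)
      if (is.finite(m) && m > 0) ratio_pop / m else ratio_pop
    }, by = sample]
    if (baseline == "population_median") {
      b[, `:=`(ratio = ratio_pop, baseline = "population")]
    } else {
      # auto: flag contigs whose population median density is aberrant
      pm <- base_pool[, .(lv = median(level)), by = .(sample, chrom)]
      glob <- base_pool[, .(g = median(level)), by = sample]
      pm <- merge(pm, glob, by = "sample")
      dev <- pm[, .(rel = median(lv / g)), by = chrom]
      aberrant <- dev[abs(rel - 1) > deviation_threshold, chrom]
      b[, baseline := ifelse(chrom %in% aberrant, "self", "population")]
      b[, ratio := ifelse(baseline == "self", ratio_self, ratio_pop)]
    }
  }
  bins <- b[, .(sample, chrom, start, end, norm, ratio, baseline)]
  setorder(bins, sample, chrom, start)
  contigs <- bins[, .(mean_ratio = mean(ratio, na.rm = TRUE), n_bins = .N),
                  by = .(sample, chrom)]
  structure(list(bins = bins[], contigs = contigs[], bin_size = bin_size),
            class = "dosage_profile")
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat("dosage profile: ", uniqueN(x$bins$sample), " samples x ",
      uniqueN(x$bins$chrom), " contigs (", nrow(x$bins), " bins)\n", sep = "")
  invisible(x)
}

arm_of <- function(start, end, cen_bp) {
  mid <- (start + end) / 2
  ifelse(mid < cen_bp, "short", "long")
}

copies_from_ratio <- function(ratio) {
  pmin(pmax(round(2 * ratio), 0L), 4L)
}

low_confidence <- function(ratio, band) {
  x <- 2 * ratio
  dist_half <- abs(x - (floor(x) + 0.5))
  dist_half < band
}

class_from_arms <- function(cs, cl) {
  fcase(
    cs == 2L & cl == 2L, "disomic",
    cs == 1L & cl == 1L, "monosomic",
    cs == 0L & cl == 0L, "nullisomic",
    cs == 3L & cl == 3L, "trisomic",
    cs == 0L & cl >= 1L, "telosomic_long_arm",
    cl == 0L & cs >= 1L, "telosomic_short_arm",
    (cs == 1L & cl == 2L) | (cs == 2L & cl == 1L), "mono_plus_telo",
    default = "partial"
  )
}

class_whole <- function(c2) {
  fcase(
    c2 == 2L, "disomic",
    c2 == 1L, "monosomic",
    c2 == 0L, "nullisomic",
    c2 == 3L, "trisomic",
    default = "partial"
  )
}

#' Classify chromosome and arm dosage
#'
#' Arm copy numbers are the nearest integer of twice the arm mean copy ratio,
#' clamped to 0..4. A call is flagged low-confidence when twice the ratio
#' falls within `band` of a half-integer (the rounding boundary). Classes are
#' derived from the arm copies; without a centromere only the
#' whole-chromosome class is reported.
#'
#' @param profile a `dosage_profile` from [compute_copy_ratio()].
#' @param centromeres optional centromere table ([read_centromeres()]).
#' @param band half-width of the low-confidence band around half-integers
#'   (default 0.15).
#' @return `data.table` with one row per sample x contig: `class_call`,
#'   `copies_short_arm`, `copies_long_arm`, `mean_ratio`, `confidence`.
#' @export
classify_dosage <- function(profile, centromeres = NULL, band = 0.15) {
  stopifnot(inherits(profile, "dosage_profile"))
  bins <- copy(profile$bins)
  whole <- bins[, .(mean_ratio = mean(ratio, na.rm = TRUE)), by = .(sample, chrom)]

  if (!is.null(centromeres)) {
    cen <- validate_centromeres(centromeres)
    bins <- merge(bins, cen[, .(chrom = contig_id, cen = centromere_bp)],
                  by = "chrom", all.x = TRUE)
    arm_means <- bins[!is.na(cen),
      .(r = mean(ratio, na.rm = TRUE)),
      by = .(sample, chrom, arm = arm_of(start, end, cen))]
    aw <- dcast(arm_means, sample + chrom ~ arm, value.var = "r")
    if (!"short" %in% names(aw)) aw[, short := NA_real_]
    if (!"long" %in% names(aw)) aw[, long := NA_real_]
    out <- merge(whole, aw, by = c("sample", "chrom"), all.x = TRUE)
  } else {
    out <- copy(whole)[, `:=`(short = NA_real_, long = NA_real_)]
  }

  out[, `:=`(
    copies_short_arm = ifelse(is.na(short), NA_integer_, copies_from_ratio(short)),
    copies_long_arm = ifelse(is.na(long), NA_integer_, copies_from_ratio(long))
  )]
  out[, class_call := ifelse(
    is.na(copies_short_arm) | is.na(copies_long_arm),
    class_whole(copies_from_ratio(mean_ratio)),
    class_from_arms(copies_short_arm, copies_long_arm)
  )]
  out[, confidence := {
    lc <- rep(FALSE, .N)
    lc <- lc | (!is.na(short) & low_confidence(short, band))
    lc <- lc | (!is.na(long) & low_confidence(long, band))
    lc <- lc | (is.na(short) & low_confidence(mean_ratio, band))
    ifelse(lc, "low", "ok")
  }]
  setnames(out, c("short", "long"), c("arm_ratio_short", "arm_ratio_long"))
  setorder(out, sample, chrom)
  out[]
}

#' Flag blank and failed samples from read totals
#'
#' Blanks (from the sample sheet) pass when below `blank_threshold` of the
#' mean non-blank total, mirroring [check_blanks()]. Non-blank samples whose
#' total is below `failure_fraction` of the non-blank mean are flagged
#' `failed`; failed samples and blanks must not enter population baselines.
#'
#' @param totals named numeric vector (or `data.table` with `sample`,
#'   `total`) of counted units per sample.
#' @param sheet optional sample sheet identifying blanks; when `NULL`, no
#'   sample is treated as a blank.
#' @param failure_fraction failure cutoff as a fraction of the non-blank
#'   mean (default 0.05).
#' @param blank_threshold blank-pass cutoff (default 1e-4 = 0.01%).
#' @return `data.table` with columns `sample`, `total`, `status` in
#'   `ok`, `failed`, `blank_pass`, `blank_fail`.
#' @export
detect_failed_and_blank <- function(totals, sheet = NULL,
                                    failure_fraction = 0.05,
                                    blank_threshold = 1e-4) {
  if (is.data.frame(totals)) {
    tt <- as.data.table(totals)[, .(sample, total)]
  } else {
    tt <- data.table(sample = names(totals), total = as.numeric(totals))
  }
  stopifnot(nrow(tt) >= 2L)
  blanks <- character(0)
  if (!is.null(sheet)) {
    sh <- validate_sample_sheet(sheet)
    blanks <- sh[is_blank == TRUE, sample_id]
  }
  tt[, is_blank := sample %in% blanks]
  mu <- mean(tt$total[!tt$is_blank])
  tt[, status := fifelse(
    is_blank, fifelse(total / mu < blank_threshold, "blank_pass", "blank_fail"),
    fifelse(total < failure_fraction * mu, "failed", "ok")
  )]
  tt[, .(sample, total, status)]
}

#' Detect alien chromosome additions on a hybrid catalog
#'
#' For each donor-genome contig of a hybrid reference, the fraction of its
#' bins whose copy ratio (relative to the sample's own background-genome
#' disomic level) exceeds `presence_threshold` decides its status: `present`
#' when at least `present_frac` of bins exceed it, `partial` when between
#' `partial_frac` and `present_frac` do (a translocated or broken
#' chromosome), `absent` otherwise.
#'
#' @param x normalized `bin_counts` over a hybrid catalog.
#' @param catalog the hybrid [genome_catalog()].
#' @param donor_label source-genome label of the alien (addition) genome.
#' @param presence_threshold ratio above which a bin counts as covered
#'   (default 0.25, half the single-copy expectation of 0.5).
#' @param present_frac,partial_frac bin-fraction cutoffs (defaults 0.8 / 0.2).
#' @return list with `calls` (sample x donor contig status and covered-bin
#'   fraction) and `summary` (per-sample number of present contigs plus the
#'   population min/median/max).
#' @export
detect_alien_additions <- function(x, catalog, donor_label,
                                   presence_threshold = 0.25,
                                   present_frac = 0.8, partial_frac = 0.2) {
  catalog <- validate_catalog(catalog)
  labs <- unique(catalog$source_genome)
  if (length(labs) < 2L) stop("catalog must have at least two source genomes")
  if (!donor_label %in% labs) stop("donor label not in catalog")
  donor_contigs <- catalog[source_genome == donor_label, contig_id]

  b <- as.data.table(x)[, .(sample, chrom, start, end, norm)]
  bin_size <- attr(x, "bin_size") %||% max(b$end - b$start)
  b[, level := norm / ((end - start) / bin_size)]
  bg <- b[!(chrom %in% donor_contigs), .(base = median(level)), by = sample]
  b <- merge(b[chrom %in% donor_contigs], bg, by = "sample")
  b[, ratio := ifelse(base > 0, level / base, NA_real_)]

  calls <- b[, .(frac = mean(ratio > presence_threshold, na.rm = TRUE),
                 n_bins = .N), by = .(sample, chrom)]
  calls[, status := fifelse(frac >= present_frac, "present",
                     fifelse(frac >= partial_frac, "partial", "absent"))]
  smry <- calls[, .(n_present = sum(status == "present")), by = sample]
  list(calls = calls[], summary = list(
    per_sample = smry[],
    min = min(smry$n_present), median = median(smry$n_present),
    max = max(smry$n_present)))
}
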