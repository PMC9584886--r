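test_that("identical samples give unit copy ratios everywhere", {
  cat1 <- tiny_catalog(c(chrA = 30e6, chrB = 30e6))
  one <- data.table::data.table(
    chrom = rep(c("chrA", "chrB"), each = 30),
    start = rep(seq(0, 29e6, 1e6), 2), end = rep(seq(1e6, 30e6, 1e6), 2),
    raw = 50L)
  bins <- data.table::rbindlist(lapply(sprintf("s%d", 1:4), function(s)
    data.table::copy(one)[, `:=`(sample = s, norm = NA_real_)]))
  x <- skimseqr:::new_bin_counts(bins, NULL, "pairs", 1e6)
  x <- normalize_bin_counts(x)
  for (b in c("population_median", "self_genome_median")) {
    pr <- compute_copy_ratio(x, baseline = b)
    expect_equal(pr$bins$ratio, rep(1, nrow(pr$bins)))
  }
})

test_that("a simulated monosomic chromosome lands near ratio 0.5", {
  toy <- toy_wheat_catalog()
  kary <- sim_karyotype("chr5D", 1)
  counts <- lapply(1:6, function(i) simulate_bin_counts(
    if (i == 1) kary else NULL, toy$catalog, coverage = 0.01,
    seed = 100 + i, sample_id = sprintf("s%d", i)))
  x <- normalize_bin_counts(bind_bin_counts(counts))
  pr <- compute_copy_ratio(x, baseline = "population_median")
  m <- pr$contigs[sample == "s1"]
  expect_true(m[chrom == "chr5D", mean_ratio] > 0.4 &&
              m[chrom == "chr5D", mean_ratio] < 0.6)
  expect_true(all(m[chrom != "chr5D", mean_ratio] > 0.9 &
                  m[chrom != "chr5D", mean_ratio] < 1.1))
})

test_that("arm ratios map to the documented dosage classes", {
  cen <- data.table::data.table(contig_id = "chr5D", centromere_bp = 20e6)
  mk <- function(short, long) {
    profile_from_ratios(list(chr5D = c(rep(short, 20), rep(long, 20))))
  }
  cls <- function(short, long) {
    classify_dosage(mk(short, long), cen)$class_call
  }
  # one copy of the long arm only -> long-arm telosomic
  expect_equal(cls(0.02, 0.51), "telosomic_long_arm")
  expect_equal(cls(1.0, 1.0), "disomic")
  # one telosome plus one whole chromosome -> mono_plus_telo
  expect_equal(cls(0.49, 1.02), "mono_plus_telo")
  expect_equal(cls(0.5, 0.5), "monosomic")
  expect_equal(cls(0.0, 0.0), "nullisomic")
  expect_equal(cls(1.5, 1.5), "trisomic")
  expect_equal(cls(0.51, 0.02), "telosomic_short_arm")

  k <- classify_dosage(mk(0.02, 0.51), cen)
  expect_equal(k$copies_short_arm, 0L)
  expect_equal(k$copies_long_arm, 1L)
})

test_that("ratios near rounding boundaries are flagged low-confidence", {
  cen <- data.table::data.table(contig_id = "chrA", centromere_bp = 20e6)
  pr <- profile_from_ratios(list(chrA = 0.74))  # 2*r = 1.48, near 1.5
  k <- classify_dosage(pr, cen, band = 0.15)
  expect_equal(k$confidence, "low")
  pr2 <- profile_from_ratios(list(chrA = 1.0))
  expect_equal(classify_dosage(pr2, cen)$confidence, "ok")
})

test_that("without a centromere only whole-chromosome classes are called", {
  pr <- profile_from_ratios(list(chrA = 0.5))
  k <- classify_dosage(pr, centromeres = NULL)
  expect_equal(k$class_call, "monosomic")
  expect_true(is.na(k$copies_short_arm))
})

test_that("failed and blank samples are flagged and excluded from baselines", {
  tot <- c(s1 = 10000, s2 = 11000, s3 = 200, b1 = 0.4)
  sheet <- demo_sheet(n_samples = 3, n_blanks = 1)
  sheet$sample_id <- names(tot)
  fl <- detect_failed_and_blank(tot, sheet)
  expect_equal(fl[sample == "s3", status], "failed")   # 2% of mean
  expect_equal(fl[sample == "b1", status], "blank_pass")  # 0.004% of mean
  expect_equal(fl[sample %in% c("s1", "s2"), status], c("ok", "ok"))
  # a blank with too many reads fails
  tot2 <- c(s1 = 10000, s2 = 10000, b1 = 3)
  sheet2 <- demo_sheet(n_samples = 2, n_blanks = 1)
  sheet2$sample_id <- names(tot2)
  expect_equal(detect_failed_and_blank(tot2, sheet2)[sample == "b1", status],
               "blank_fail")
  # comparable samples: no flags
  tot3 <- c(s1 = 10000, s2 = 9800)
  expect_true(all(detect_failed_and_blank(tot3)$status == "ok"))
})

test_that("alien chromosome additions are detected as present/partial/absent", {
  hy <- toy_hybrid_catalog(donor_chroms = c("chr1H", "chr2H", "chr3H"),
                           donor_len_mb = c(520, 600, 640))
  # sample 1 carries chr3H (disomic addition), sample 2 nothing,
  # sample 3 carries only half of chr2H
  k1 <- sim_karyotype(c("barley_chr1H", "barley_chr2H", "barley_chr3H"),
                      c(0, 0, 2))
  k2 <- sim_karyotype(c("barley_chr1H", "barley_chr2H", "barley_chr3H"),
                      c(0, 0, 0))
  k3 <- sim_karyotype(c("barley_chr1H", "barley_chr2H", "barley_chr2H",
                        "barley_chr3H"), c(0, 2, 0, 0),
                      start_bp = c(NA, 0, 300e6, NA),
                      end_bp = c(NA, 300e6, 600e6, NA))
  counts <- mapply(function(k, s, sd) simulate_bin_counts(
    k, hy$catalog, coverage = 0.03, seed = sd, sample_id = s),
    list(k1, k2, k3), c("a1", "a2", "a3"), c(31, 32, 33), SIMPLIFY = FALSE)
  x <- normalize_bin_counts(bind_bin_counts(counts))
  res <- detect_alien_additions(x, hy$catalog, "barley")
  calls <- res$calls
  expect_equal(calls[sample == "a1" & chrom == "barley_chr3H", status],
               "present")
  expect_equal(calls[sample == "a1" & chrom == "barley_chr1H", status],
               "absent")
  expect_true(all(calls[sample == "a2", status] == "absent"))
  expect_equal(calls[sample == "a3" & chrom == "barley_chr2H", status],
               "partial")
  expect_equal(res$summary$per_sample[sample == "a1", n_present], 1L)
})

test_that("increasing simulated copy number never decreases called copies", {
  toy <- toy_wheat_catalog()
  called <- vapply(0:3, function(cp) {
    k <- if (cp == 2) NULL else sim_karyotype("chr3B", cp)
    x <- normalize_bin_counts(simulate_bin_counts(
      k, toy$catalog, coverage = 0.05, seed = 700 + cp))
    pr <- compute_copy_ratio(x, baseline = "self_genome_median")
    kk <- classify_dosage(pr, toy$centromeres)
    kk[chrom == "chr3B", copies_short_arm + copies_long_arm]
  }, numeric(1))
  expect_true(all(diff(called) >= 0))
})
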