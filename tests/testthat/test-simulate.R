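test_that("bin-count simulation respects copy number and the Poisson mean", {
  cat1 <- tiny_catalog(c(chrA = 100e6, chrB = 100e6))
  k <- sim_karyotype(c("chrA", "chrB"), c(0, 1),
                     start_bp = c(20e6, NA), end_bp = c(60e6, NA))
  x <- simulate_bin_counts(k, cat1, coverage = 0.025, seed = 5)
  # copy-0 interval is exactly zero
  expect_true(all(x[chrom == "chrA" & start >= 20e6 & start < 60e6, raw] == 0L))
  # disomic lambda = cov * bin / (2 * rl) = 83.33; 3-SE moment check
  lam <- 0.025 * 1e6 / 300
  dis <- x[chrom == "chrA" & (start < 20e6 | start >= 60e6), raw]
  mono <- x[chrom == "chrB", raw]
  expect_lt(abs(mean(dis) - lam), 3 * sqrt(lam / length(dis)))
  # monosomic mean is about half the disomic mean
  expect_lt(abs(mean(mono) - lam / 2), 3 * sqrt(lam / 2 / length(mono)))
})

test_that("generators are pure functions of config and seed", {
  cat1 <- tiny_catalog(c(chrA = 50e6))
  a <- simulate_bin_counts(NULL, cat1, 0.1, seed = 9)
  b <- simulate_bin_counts(NULL, cat1, 0.1, seed = 9)
  expect_identical(a$raw, b$raw)
  c2 <- simulate_bin_counts(NULL, cat1, 0.1, seed = 10)
  expect_false(identical(a$raw, c2$raw))
})

test_that("simulated totals recover the configured coverage via the pool equation", {
  cat1 <- tiny_catalog(c(chrA = 500e6, chrB = 500e6))
  cov <- 0.05
  x <- simulate_bin_counts(NULL, cat1, cov, seed = 12)
  est <- estimate_coverage(sum(x$raw), 150, sum(cat1$length_bp), 1)
  lam_tot <- cov * sum(cat1$length_bp) / 300
  se <- sqrt(lam_tot) / lam_tot * cov
  expect_lt(abs(est - cov), 3 * se)
})

test_that("overdispersion inflates variance but keeps the mean", {
  cat1 <- tiny_catalog(c(chrA = 2000e6))
  p <- simulate_bin_counts(NULL, cat1, 0.05, seed = 14)
  nb <- simulate_bin_counts(NULL, cat1, 0.05, seed = 14, dispersion = 0.3)
  expect_equal(mean(nb$raw), mean(p$raw), tolerance = 0.05)
  expect_gt(var(nb$raw), 1.5 * var(p$raw))
})

test_that("simulated SAM round-trips through filter and binning exactly", {
  d <- withr::local_tempdir()
  cat1 <- genome_catalog(c("c1", "c2"), c(4e6, 3e6), "toy")
  sim <- simulate_sam(sim_karyotype("c2", 1), cat1, coverage = 0.3,
                      seed = 8, out_sam = file.path(d, "s.sam"),
                      bin_size_bp = 5e5, multimapper_fraction = 0.2)
  st <- filter_unique_concordant(file.path(d, "s.sam"),
                                 file.path(d, "f.bam"))
  expect_equal(st$input_records, 2L * sim$n_pairs)
  expect_equal(st$kept_records, 2L * (sim$n_pairs - sim$n_multi))
  grid <- bin_grid(cat1, 5e5)
  x <- count_in_bins(file.path(d, "f.bam"), grid, sample_id = "sim")
  expect_equal(x$raw, sim$truth$raw)

  # with no multimappers the filter keeps everything
  sim0 <- simulate_sam(NULL, cat1, coverage = 0.1, seed = 3,
                       out_sam = file.path(d, "s0.sam"), bin_size_bp = 5e5)
  st0 <- filter_unique_concordant(file.path(d, "s0.sam"),
                                  file.path(d, "f0.bam"))
  expect_equal(st0$kept_records, st0$input_records)
})

test_that("monosomic panels encode their truth classes in the counts", {
  toy <- toy_wheat_catalog()
  pan <- simulate_monosomic_panel(
    catalog = toy$catalog, centromeres = toy$centromeres,
    composition = c(disomic = 3, monosomic = 3, nullisomic = 2,
                    telosomic_long_arm = 2, blank = 1),
    coverage = 0.01, seed = 77)
  expect_equal(nrow(pan$truth), 11L)
  cen5D <- toy$centromeres[contig_id == "chr5D", centromere_bp]
  x <- pan$counts
  for (i in seq_len(nrow(pan$truth))) {
    s <- pan$truth$sample[i]
    b5 <- x[sample == s & chrom == "chr5D"]
    cls <- pan$truth$class[i]
    if (cls == "nullisomic") expect_equal(sum(b5$raw), 0L)
    if (cls == "telosomic_long_arm")
      expect_equal(sum(b5[start < cen5D - 1e6, raw]), 0L)
    if (cls == "blank") expect_equal(sum(x[sample == s, raw]), 0L)
  }
  # composition must cover known classes only
  expect_error(simulate_monosomic_panel(
    catalog = toy$catalog, centromeres = toy$centromeres,
    composition = c(weird = 1), seed = 1), "unknown classes")
  # telosomics require a centromere
  expect_error(simulate_monosomic_panel(
    catalog = toy$catalog, centromeres = NULL,
    composition = c(telosomic_long_arm = 1), seed = 1), "centromere")
})

test_that("BC1 carrier draws follow the configured probability", {
  hy <- group7_hybrid()
  pop <- simulate_bc1_population(
    hy, "wheat_chr7A", 362e6, 473e6, "barley_chr7H", 337e6, 456e6,
    n_samples = 60, carrier_prob = 1, coverage = 0.01, seed = 15)
  expect_true(all(pop$truth$carrier))
  pop2 <- simulate_bc1_population(
    hy, "wheat_chr7A", 362e6, 473e6, "barley_chr7H", 337e6, 456e6,
    n_samples = 335, carrier_prob = 0.5, coverage = 0.005, seed = 16)
  n_car <- sum(pop2$truth$carrier)
  expect_lt(abs(n_car - 167.5), 3 * sqrt(335 * 0.25))
})

test_that("DH simulation respects crossover and observation models", {
  cat1 <- genome_catalog(c("chr1", "chr2"), c(200e6, 200e6), "wheat")
  mm <- sim_marker_map(cat1, 1e5)
  # no crossovers: each chromosome is single-parent
  dh0 <- simulate_dh_population(mm, cat1, n_samples = 6, coverage = 0.05,
                                crossover_mean_per_chrom = 0, seed = 44)
  per_chrom <- dh0$truth[, .(n_par = data.table::uniqueN(parent)),
                         by = .(sample, chrom)]
  expect_true(all(per_chrom$n_par == 1L))
  # observed fraction matches 1 - exp(-coverage) within 3 SE
  p_obs <- 1 - exp(-0.05)
  obs <- mean(dh0$calls$call != "missing")
  n <- nrow(dh0$calls)
  expect_lt(abs(obs - p_obs), 3 * sqrt(p_obs * (1 - p_obs) / n))
})

test_that("karyotype overrides reject overlaps and negative copies", {
  expect_error(sim_karyotype("c1", -1), ">= 0")
  expect_error(sim_karyotype(c("c1", "c1"), c(1, 2),
                             start_bp = c(0, 5e6), end_bp = c(10e6, 15e6)),
               "overlapping")
  expect_error(sim_karyotype(c("c1", "c1"), c(1, 2),
                             start_bp = c(NA, 5e6), end_bp = c(NA, 15e6)),
               "whole-contig")
})
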