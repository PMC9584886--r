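test_that("bin grid is contiguous with a truncated last bin", {
  g <- bin_grid(tiny_catalog(c(chrA = 2500000)), 1e6)
  expect_equal(g$start, c(0, 1e6, 2e6))
  expect_equal(g$end, c(1e6, 2e6, 2.5e6))
  expect_error(bin_grid(tiny_catalog(), -1), "bin_size")
})

test_that("pairs are counted at the leftmost mate position", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "t.sam")
  # 5 pairs at hand-placed positions on two contigs
  pos <- list(c("chrA", 1500000), c("chrA", 1999951), c("chrA", 2000001),
              c("chrB", 1), c("chrB", 999999))
  recs <- unlist(lapply(seq_along(pos), function(i) c(
    sam_record(paste0("p", i), 99, pos[[i]][1], as.integer(pos[[i]][2]),
               as.integer(pos[[i]][2]) + 250),
    sam_record(paste0("p", i), 147, pos[[i]][1],
               as.integer(pos[[i]][2]) + 250, as.integer(pos[[i]][2])))))
  o <- order(vapply(rep(seq_along(pos), each = 2), function(i) pos[[i]][1],
                    character(1)))
  write_sam(sam, c(chrA = 4000000, chrB = 3000000), recs)

  grid <- bin_grid(tiny_catalog(c(chrA = 4e6, chrB = 3e6)), 1e6)
  x <- count_in_bins(sam, grid, sample_id = "s1", unit = "pairs")
  expect_equal(x[chrom == "chrA", raw], c(0L, 2L, 1L, 0L))
  expect_equal(x[chrom == "chrB", raw], c(2L, 0L, 0L))
  # conservation: total equals number of pairs
  expect_equal(sum(x$raw), 5L)
  expect_equal(unname(bin_totals(x)), 5L)

  # unit = reads counts each mate in its own bin
  xr <- count_in_bins(sam, grid, sample_id = "s1", unit = "reads")
  expect_equal(sum(xr$raw), 10L)
})

test_that("alignments on contigs outside the grid go to the unplaced bucket", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "t.sam")
  write_sam(sam, c(chrA = 2000000, chrUn = 2000000), c(
    sam_record("p1", 99, "chrA", 100, 350),
    sam_record("p1", 147, "chrA", 350, 100),
    sam_record("p2", 99, "chrUn", 100, 350),
    sam_record("p2", 147, "chrUn", 350, 100)))
  grid <- bin_grid(tiny_catalog(c(chrA = 2e6)), 1e6)
  expect_message(x <- count_in_bins(sam, grid), "unplaced")
  expect_equal(attr(x, "unplaced"), 1L)
  expect_equal(sum(x$raw), 1L)
})

test_that("normalization follows the reads-per-factor arithmetic", {
  x <- data.table::data.table(
    sample = "s1", chrom = "chrA", start = c(0, 1e6), end = c(1e6, 2e6),
    raw = c(70L, 30L), norm = NA_real_)
  x <- skimseqr:::new_bin_counts(x, c(s1 = 1e6), "pairs", 1e6)
  # raw 70, total 1e6, factor 1e7 -> 700
  n1 <- normalize_bin_counts(x, factor = 1e7, totals = c(s1 = 1e6))
  expect_equal(n1$norm, c(700, 300))
  # factor equal to the total is the identity
  n2 <- normalize_bin_counts(x, factor = 100, totals = c(s1 = 100))
  expect_equal(n2$norm, as.numeric(x$raw))
  # mean_bin mode: raw 50 with per-bin mean 25 -> 2.0
  y <- data.table::data.table(
    sample = "s1", chrom = "chrA", start = c(0, 1e6), end = c(1e6, 2e6),
    raw = c(50L, 0L), norm = NA_real_)
  y <- skimseqr:::new_bin_counts(y, c(s1 = 50), "pairs", 1e6)
  n3 <- normalize_bin_counts(y, mode = "mean_bin")
  expect_equal(n3$norm, c(2, 0))
  # zero-total sample flagged failed with norm 0
  z <- data.table::data.table(
    sample = "s0", chrom = "chrA", start = 0, end = 1e6, raw = 0L,
    norm = NA_real_)
  z <- skimseqr:::new_bin_counts(z, c(s0 = 0), "pairs", 1e6)
  nz <- normalize_bin_counts(z)
  expect_equal(nz$norm, 0)
  expect_equal(attr(nz, "failed_samples"), "s0")
})

test_that("fixed-factor norm sums to the factor when all reads are binned", {
  cat1 <- tiny_catalog(c(chrA = 50e6, chrB = 50e6))
  x <- simulate_bin_counts(NULL, cat1, coverage = 0.1, seed = 4)
  n <- normalize_bin_counts(x, factor = 1e7)
  expect_equal(sum(n$norm), 1e7)
})

test_that("pooled coverage arithmetic matches the published examples", {
  # wheat-barley pool: 485,575,828 spots, 150 bp, 15 Gb, 384 samples
  expect_equal(estimate_coverage(485575828, 150, 15e9, 384), 0.0253,
               tolerance = 0.01)
  # wheatgrass pool: 359,405,323 spots, 150 bp, 12 Gb, 288 samples
  expect_equal(estimate_coverage(359405323, 150, 12e9, 288), 0.0312,
               tolerance = 0.01)
  expect_equal(estimate_coverage(0, 150, 15e9, 384), 0)
  expect_error(estimate_coverage(10, 150, -1, 4))
})

test_that("effective depth converts mean pairs per bin to coverage", {
  expect_equal(effective_depth_from_bin_mean(30.6, 150, 1e6), 0.00918)
  expect_equal(effective_depth_from_bin_mean(0, 150, 1e6), 0)
  # inversion consistency: 83.3 pairs/Mb ~ 0.025x
  expect_equal(effective_depth_from_bin_mean(83.3, 150, 1e6), 0.025,
               tolerance = 0.001)
})

test_that("unknown contigs are removed by pattern", {
  x <- data.table::data.table(
    sample = "s1", chrom = c("chr1A", "chrUn", "scaffold_unplaced_1"),
    start = 0, end = 1e6, raw = 1L, norm = 1)
  x <- skimseqr:::new_bin_counts(x, c(s1 = 3), "pairs", 1e6)
  out <- drop_unknown_contigs(x)
  expect_equal(out$chrom, "chr1A")
  expect_equal(attr(out, "n_removed"), 2L)
  y <- drop_unknown_contigs(x, patterns = "no_such_pattern")
  expect_equal(nrow(y), 3L)
  expect_error(drop_unknown_contigs(x, patterns = "."), "all rows")
})

test_that("per-chromosome densities identify extremes", {
  x <- data.table::data.table(
    sample = rep("s1", 4),
    chrom = rep(c("chrA", "chrB"), each = 2),
    start = rep(c(0, 1e6), 2), end = rep(c(1e6, 2e6), 2),
    raw = c(10L, 20L, 40L, 60L), norm = c(1, 2, 4, 6))
  x <- skimseqr:::new_bin_counts(x, c(s1 = 130), "pairs", 1e6)
  dens <- per_chromosome_density(x)
  expect_equal(dens$population[chrom == "chrA", mean_raw], 15)
  expect_equal(dens$population[chrom == "chrB", mean_raw], 50)
  expect_equal(dens$min_contig, "chrA")
  expect_equal(dens$max_contig, "chrB")
})

test_that("bin-count TSVs round-trip with their metadata", {
  d <- withr::local_tempdir()
  cat1 <- tiny_catalog(c(chrA = 5e6))
  x <- normalize_bin_counts(simulate_bin_counts(NULL, cat1, 0.5, seed = 1))
  p <- file.path(d, "bins.tsv")
  write_bin_counts(x, p)
  y <- read_bin_counts(p)
  expect_equal(y$raw, x$raw)
  expect_equal(y$norm, x$norm)
  expect_equal(attr(y, "unit"), "pairs")
  expect_equal(attr(y, "bin_size"), 1e6)
  expect_equal(bin_totals(y), bin_totals(x))
})
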