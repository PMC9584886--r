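test_that("exact-match demultiplexing assigns hand-enumerable pairs", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 2, n_blanks = 0)
  # 4 pairs: two for each sample, exact barcodes
  ids <- paste0("r", 1:4)
  write_fastq_records(file.path(d, "R1.fq"), ids, rep("ACGTACGT", 4))
  write_fastq_records(file.path(d, "R2.fq"), ids, rep("TTTTAAAA", 4))
  write_fastq_records(file.path(d, "I1.fq"), ids,
                      sheet$i7[c(1, 2, 1, 2)])
  write_fastq_records(file.path(d, "I2.fq"), ids,
                      sheet$i5[c(1, 2, 1, 2)])
  rep <- demultiplex(file.path(d, "R1.fq"), file.path(d, "R2.fq"),
                     file.path(d, "I1.fq"), file.path(d, "I2.fq"),
                     sheet, file.path(d, "out"), max_mismatch = 0)
  expect_equal(rep$counts$n_pairs, c(2L, 2L))
  expect_equal(rep$undetermined, 0L)
  expect_equal(sum(rep$counts$n_pairs) + rep$undetermined, rep$total)
  # partitioned files hold the right records
  s1 <- Biostrings::readDNAStringSet(file.path(d, "out", "s01_R1.fastq"),
                                     format = "fastq")
  expect_equal(sub("\\s.*$", "", names(s1)), c("r1", "r3"))
})

test_that("unmatched and ambiguous index pairs are undetermined", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 2, n_blanks = 0)
  ids <- paste0("r", 1:3)
  write_fastq_records(file.path(d, "R1.fq"), ids, rep("ACGTACGT", 3))
  write_fastq_records(file.path(d, "R2.fq"), ids, rep("ACGTACGT", 3))
  # r1 matches s01; r2 matches nothing; r3 is 1 mismatch from s01's i7
  write_fastq_records(file.path(d, "I1.fq"), ids,
                      c(sheet$i7[1], "GGGGGG", sub("^A", "T", sheet$i7[1])))
  write_fastq_records(file.path(d, "I2.fq"), ids, rep(sheet$i5[1], 3))
  rep0 <- demultiplex(file.path(d, "R1.fq"), file.path(d, "R2.fq"),
                      file.path(d, "I1.fq"), file.path(d, "I2.fq"),
                      sheet, file.path(d, "o0"), max_mismatch = 0)
  expect_equal(rep0$counts$n_pairs, c(1L, 0L))
  expect_equal(rep0$undetermined, 2L)
  # with 1 mismatch allowed, r3 is recovered
  rep1 <- demultiplex(file.path(d, "R1.fq"), file.path(d, "R2.fq"),
                      file.path(d, "I1.fq"), file.path(d, "I2.fq"),
                      sheet, file.path(d, "o1"), max_mismatch = 1)
  expect_equal(rep1$counts$n_pairs, c(2L, 0L))
  expect_equal(rep1$undetermined, 1L)
})

test_that("desynchronized streams and bad sheets are fatal", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 2, n_blanks = 0)
  write_fastq_records(file.path(d, "R1.fq"), c("a", "b"), rep("ACGT", 2))
  write_fastq_records(file.path(d, "R2.fq"), c("a", "c"), rep("ACGT", 2))
  write_fastq_records(file.path(d, "I1.fq"), c("a", "b"), rep(sheet$i7[1], 2))
  write_fastq_records(file.path(d, "I2.fq"), c("a", "b"), rep(sheet$i5[1], 2))
  expect_error(demultiplex(file.path(d, "R1.fq"), file.path(d, "R2.fq"),
                           file.path(d, "I1.fq"), file.path(d, "I2.fq"),
                           sheet, file.path(d, "o")), "desynchronized")
  bad <- data.table::copy(sheet)[, sample_id := "dup"]
  expect_error(validate_sample_sheet(bad), "duplicate sample_id")
  bad2 <- data.table::copy(sheet)
  bad2$i7[1] <- "ACGTAN"
  expect_error(validate_sample_sheet(bad2), "alphabet")
})

test_that("i5 orientation is detected by majority exact-match rate", {
  sheet <- demo_sheet(n_samples = 4, n_blanks = 0)
  i5s <- sheet$i5
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(i5s)))
  expect_equal(detect_i5_orientation(rep(i5s, 25), sheet), "as-is")
  expect_equal(detect_i5_orientation(rep(rc, 25), sheet),
               "reverse-complement")
  # 60/40 split goes to the majority
  expect_equal(detect_i5_orientation(c(rep(rc[1], 60), rep(i5s[1], 40)),
                                     sheet), "reverse-complement")
  expect_equal(detect_i5_orientation(c(rep(i5s[1], 60), rep(rc[1], 40)),
                                     sheet), "as-is")
  expect_warning(detect_i5_orientation(rep("TTTTTT", 5), sheet),
                 "either orientation")
})

test_that("blank wells pass below 0.01% of the non-blank mean", {
  counts <- data.table::data.table(
    sample_id = c("a", "b", "blank"),
    is_blank = c(FALSE, FALSE, TRUE),
    n_pairs = c(10000L, 10000L, 0L))
  expect_true(check_blanks(counts)$pass)
  counts$n_pairs[3] <- 3L  # 0.03% of mean
  expect_false(check_blanks(counts)$pass)
  # boundary arithmetic: 0.009% of mean passes
  counts2 <- data.table::data.table(
    sample_id = c("a", "b", "blank"),
    is_blank = c(FALSE, FALSE, TRUE),
    n_pairs = c(100000L, 100000L, 9L))
  expect_true(check_blanks(counts2)$pass)
})

test_that("simulated multiplexed runs round-trip exactly, both orientations", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 6, n_blanks = 1)
  for (ori in c("as-is", "reverse-complement")) {
    sim <- simulate_index_reads(sheet, file.path(d, ori),
                                reads_per_sample = 30, error_rate = 0,
                                orientation = ori, seed = 11)
    rep <- demultiplex(sim$files["R1"], sim$files["R2"],
                       sim$files["I1"], sim$files["I2"],
                       sheet, file.path(d, paste0(ori, "_out")))
    expect_equal(rep$orientation, ori)
    m <- merge(rep$counts, sim$truth, by = "sample_id")
    expect_equal(m$n_pairs.x, m$n_pairs.y)
    expect_equal(sum(rep$counts$n_pairs) + rep$undetermined, rep$total)
    expect_true(all(rep$blanks$pass))
  }
})

test_that("index errors recover more pairs with mismatch tolerance", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 6, n_blanks = 0)
  sim <- simulate_index_reads(sheet, d, reads_per_sample = 60,
                              error_rate = 0.01, seed = 5)
  r0 <- demultiplex(sim$files["R1"], sim$files["R2"], sim$files["I1"],
                    sim$files["I2"], sheet, file.path(d, "o0"),
                    max_mismatch = 0)
  r1 <- demultiplex(sim$files["R1"], sim$files["R2"], sim$files["I1"],
                    sim$files["I2"], sheet, file.path(d, "o1"),
                    max_mismatch = 1)
  expect_gt(sum(r1$counts$n_pairs), sum(r0$counts$n_pairs))
})

test_that("header-embedded barcodes are an accepted input mode", {
  d <- withr::local_tempdir()
  sheet <- demo_sheet(n_samples = 2, n_blanks = 0)
  ids <- paste0("r", 1:4)
  cm <- paste0("1:N:0:", sheet$i7[c(1, 2, 1, 2)], "+", sheet$i5[c(1, 2, 1, 2)])
  write_fastq_records(file.path(d, "R1.fq"), ids, rep("ACGTACGT", 4), cm)
  write_fastq_records(file.path(d, "R2.fq"), ids, rep("ACGTACGT", 4), cm)
  rep <- demultiplex(file.path(d, "R1.fq"), file.path(d, "R2.fq"),
                     i1 = NULL, i2 = NULL, sheet, file.path(d, "out"))
  expect_equal(rep$counts$n_pairs, c(2L, 2L))
})
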