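plate_sheet_with_primers <- function() {
  plate_sample_sheet(fwd_primer = test_fwd_primer(),
                     rev_primer = test_rev_primer())
}

test_that("error-free reads start with the embedded tags on both mates", {
  sheet <- plate_sheet_with_primers()
  sim <- simulate_reads(sheet, reads_per_sample = 2, read_length = 50,
                        insert_length = 60, error_rate = 0, seed = 2)
  full <- tag_sequence(sheet$index_set)
  ftag <- unname(full[sim$truth$fwd_tag])
  rtag <- unname(full[sim$truth$rev_tag])
  expect_true(all(substr(sim$r1$seq, 1, nchar(ftag)) == ftag))
  # strand convention: R2 begins with the reverse spacer+index 5'->3'
  expect_true(all(substr(sim$r2$seq, 1, nchar(rtag)) == rtag))
  # after the tag comes the locus primer (no degenerate codes here)
  expect_true(all(substr(sim$r1$seq, nchar(ftag) + 1,
                         nchar(ftag) + 18) ==
                  test_fwd_primer()$sequence))
})

test_that("record counts, truth entries, and insert coordinates agree", {
  sheet <- plate_sheet_with_primers()
  dir <- withr::local_tempdir()
  sim <- simulate_reads(sheet, out_dir = dir, reads_per_sample = 10,
                        read_length = 50, insert_length = 60,
                        error_rate = 0, seed = 4)
  expect_equal(nrow(sim$truth), 960L)
  expect_equal(anyDuplicated(sim$truth$id), 0L)
  f1 <- amplitag:::.read_fastq(sim$r1_path)
  f2 <- amplitag:::.read_fastq(sim$r2_path)
  expect_equal(length(f1$seq), 960L)
  expect_equal(length(f2$seq), 960L)
  expect_true(all(nchar(f1$seq) == 50L))
  expect_true(all(nchar(f1$qual) == 50L))

  # 0-based half-open insert coordinates address the insert on R1
  i <- 1L
  start <- sim$truth$r1_insert_start[i]
  end <- sim$truth$r1_insert_end[i]
  expect_equal(start,
               nchar(tag_sequence(sheet$index_set)[[sim$truth$fwd_tag[i]]]) +
               18L)
  expect_true(end <= 50L)
  expect_true(end > start)
})

test_that("simulation is deterministic for a fixed seed", {
  sheet <- plate_sheet_with_primers()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_reads(sheet, out_dir = d1, reads_per_sample = 3,
                       read_length = 45, insert_length = 50,
                       error_rate = 0.02, seed = 123, compress = FALSE)
  s2 <- simulate_reads(sheet, out_dir = d2, reads_per_sample = 3,
                       read_length = 45, insert_length = 50,
                       error_rate = 0.02, seed = 123, compress = FALSE)
  expect_identical(readLines(s1$r1_path), readLines(s2$r1_path))
  expect_identical(readLines(s1$r2_path), readLines(s2$r2_path))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the reads
  s3 <- simulate_reads(sheet, reads_per_sample = 3, read_length = 45,
                       insert_length = 50, error_rate = 0.02, seed = 124)
  expect_false(identical(s1$r1$seq, s3$r1$seq))
})

test_that("guards reject unusable simulation parameters", {
  sheet <- plate_sheet_with_primers()
  expect_error(simulate_reads(sheet, read_length = 20, seed = 1),
               "read_length must be at least")
  expect_error(simulate_reads(sheet, error_rate = 0.7, seed = 1),
               "error_rate")
  expect_error(simulate_reads(plate_sample_sheet(), seed = 1),
               "fwd_primer")
  empty <- plate_sheet_with_primers()
  empty$entries <- empty$entries[0, ]
  expect_error(simulate_reads(empty, seed = 1), "empty sample sheet")
})

test_that("perfect demux scores 1.0 and a shuffled one near chance", {
  sheet <- plate_sheet_with_primers()
  sim <- simulate_reads(sheet, reads_per_sample = 5, read_length = 50,
                        insert_length = 60, error_rate = 0, seed = 8)
  dir <- withr::local_tempdir()
  amplitag:::.write_fastq(sim$r1$id, sim$r1$seq, sim$r1$qual,
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(sim$r2$id, sim$r2$seq, sim$r2$qual,
                          file.path(dir, "r2.fastq"))
  st <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                  sheet, NULL)
  sc <- score_demux(st, sim$truth)
  expect_equal(sc$fraction_correct, 1.0)
  expect_equal(sc$fraction_correct + sc$fraction_misassigned +
               sc$fraction_unassigned, 1.0)

  # permutation baseline: shuffled labels land near 1 / n_samples
  set.seed(1)
  shuffled <- st$assignments
  shuffled$sample <- sample(shuffled$sample)
  sc2 <- score_demux(shuffled[, c("id", "sample", "category")],
                     sim$truth)
  expect_lt(abs(sc2$fraction_correct - 1 / 96), 0.02)

  bad <- st$assignments[-1, ]
  expect_error(score_demux(bad[, c("id", "sample", "category")],
                           sim$truth), "universes differ")
})

test_that("one substitution per tag: max_dist 1 recovers all, 0 assigns none wrongly", {
  sheet <- plate_sheet_with_primers()
  sim <- simulate_reads(sheet, reads_per_sample = 2, read_length = 50,
                        insert_length = 60, error_rate = 0, seed = 9)
  full <- tag_sequence(sheet$index_set)
  set.seed(10)
  corrupt <- function(seqs, tags) {
    lens <- nchar(unname(full[tags]))
    vapply(seq_along(seqs), function(i) {
      p <- sample.int(lens[i], 1L)
      b <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      seqs[i]
    }, character(1L))
  }
  r1 <- corrupt(sim$r1$seq, sim$truth$fwd_tag)
  r2 <- corrupt(sim$r2$seq, sim$truth$rev_tag)
  dir <- withr::local_tempdir()
  amplitag:::.write_fastq(sim$r1$id, r1, sim$r1$qual,
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(sim$r2$id, r2, sim$r2$qual,
                          file.path(dir, "r2.fastq"))

  st1 <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                   sheet, NULL, max_dist = 1)
  sc1 <- score_demux(st1, sim$truth)
  # the design guarantee is zero misassignment: a damaged tag is either
  # recovered or -- when it ties with a different-length candidate at
  # equal distance -- refused as ambiguous, never given to a wrong sample
  expect_equal(sc1$fraction_misassigned, 0.0)
  expect_gt(sc1$fraction_correct, 0.9)
  expect_equal(st1$categories[["unassigned_no_tag"]], 0L)
  expect_equal(sc1$fraction_correct + sc1$fraction_unassigned, 1.0)

  st0 <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                   sheet, NULL, max_dist = 0)
  sc0 <- score_demux(st0, sim$truth)
  expect_equal(sc0$fraction_misassigned, 0.0)
  expect_equal(sc0$fraction_unassigned, 1.0)
})

test_that("injected tag jumps surface as unexpected combinations", {
  # diagonal sheet: any jumped reverse tag leaves the sheet's key space
  entries <- data.frame(sample_id = sprintf("S%02d", 1:8),
                        fwd_tag = LETTERS[1:8],
                        rev_tag = as.character(1:8))
  sheet <- sample_sheet(entries, fwd_primer = test_fwd_primer(),
                        rev_primer = test_rev_primer())
  sim <- simulate_reads(sheet, reads_per_sample = 30, read_length = 50,
                        insert_length = 60, error_rate = 0,
                        tag_jump_rate = 0.2, seed = 21)
  expect_gt(sum(sim$truth$tag_jumped), 0)
  dir <- withr::local_tempdir()
  amplitag:::.write_fastq(sim$r1$id, sim$r1$seq, sim$r1$qual,
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(sim$r2$id, sim$r2$seq, sim$r2$qual,
                          file.path(dir, "r2.fastq"))
  st <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                  sheet, NULL)
  # on a diagonal sheet every swapped reverse tag leaves the key space
  n_jumped <- sum(sim$truth$tag_jumped)
  expect_equal(st$categories[["unexpected_combination"]], n_jumped)
  # the tag-pair matrix records the off-diagonal observations
  offdiag <- sum(st$pair_matrix) - sum(diag(st$pair_matrix[, 1:8]))
  expect_equal(offdiag, n_jumped)
})

test_that("outer i5/i7 header labels can veto inline assignments", {
  entries <- data.frame(sample_id = c("S1", "S2"),
                        fwd_tag = c("A", "B"), rev_tag = c("1", "2"),
                        i5 = c("D501", "D502"), i7 = c("D701", "D702"))
  sheet <- sample_sheet(entries, fwd_primer = test_fwd_primer(),
                        rev_primer = test_rev_primer())
  sim <- simulate_reads(sheet, reads_per_sample = 4, read_length = 50,
                        insert_length = 60, error_rate = 0, seed = 3)
  expect_match(sim$r1$id[1], "i5=D501 i7=D701")
  dir <- withr::local_tempdir()
  # swap the header labels of S1's reads to S2's outer indexes
  ids <- sub("i5=D501 i7=D701", "i5=D502 i7=D702", sim$r1$id)
  amplitag:::.write_fastq(ids, sim$r1$seq, sim$r1$qual,
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(ids, sim$r2$seq, sim$r2$qual,
                          file.path(dir, "r2.fastq"))
  st <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                  sheet, NULL, filter_outer = TRUE)
  expect_equal(unname(st$per_sample["S1"]), 0L)
  expect_equal(unname(st$per_sample["S2"]), 4L)
  expect_equal(st$categories[["unexpected_combination"]], 4L)
})
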