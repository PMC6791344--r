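test_that("tag matching finds exact and single-error tags, rejects garbage", {
  s <- default_index_set()
  fwd <- forward_tags(s)

  m <- match_tag("GGTACAAAAAAGTCAGGTC", fwd, max_dist = 1)
  expect_equal(m$label, "A")
  expect_equal(m$distance, 0)

  # one substitution inside tag A; brute-force confirms uniqueness
  mutated <- "GGAACAAAAAAGTCAGGTC"
  dists <- vapply(unname(tag_sequence(fwd)),
                  function(t) ham_chars(mutated, t), numeric(1))
  expect_equal(sum(dists <= 1), 1L)
  m1 <- match_tag(mutated, fwd, max_dist = 1)
  expect_equal(m1$label, "A")
  expect_equal(m1$distance, 1)

  m2 <- match_tag("TTTTTTTTTTTTTTT", fwd, max_dist = 1)
  expect_true(is.na(m2$label))
  expect_equal(m2$status, "no_tag")

  # read shorter than every candidate
  m3 <- match_tag("GGT", fwd)
  expect_equal(m3$status, "no_tag")
})

test_that("same-length tags are Hamming >= 3 apart across the whole set", {
  full <- unname(tag_sequence(default_index_set()))
  for (i in seq_along(full))
    for (j in seq_along(full))
      if (i < j && nchar(full[i]) == nchar(full[j]))
        expect_gte(ham_chars(full[i], full[j]), 3)
})

test_that("no single substitution misassigns a tag at max_dist = 1", {
  # every 1-error variant of every tag, embedded ahead of a real locus
  # primer, must match its own tag or nothing -- never another tag
  s <- default_index_set()
  for (role in c("forward", "reverse")) {
    cands <- if (role == "forward") forward_tags(s) else reverse_tags(s)
    context <- if (role == "forward") test_fwd_primer()$sequence
               else test_rev_primer()$sequence
    for (i in seq_len(nrow(cands))) {
      tag <- unname(tag_sequence(cands[i, ]))
      variants <- substitution_variants(tag)
      m <- match_tag(paste0(variants, context), cands, max_dist = 1)
      wrong <- !is.na(m$label) & m$label != cands$label[i]
      expect_false(any(wrong))
      # at max_dist = 0 a damaged tag is never claimed by another tag
      m0 <- match_tag(paste0(variants, context), cands, max_dist = 0)
      expect_false(any(!is.na(m0$label) & m0$label != cands$label[i]))
    }
  }
})

test_that("demux_pair assigns, trims, and flags unexpected combinations", {
  diag_entries <- data.frame(sample_id = sprintf("S%02d", 1:8),
                             fwd_tag = LETTERS[1:8],
                             rev_tag = as.character(1:8))
  sheet <- sample_sheet(diag_entries)
  s <- default_index_set()
  full <- tag_sequence(s)

  pad <- function(tag) paste0(tag, "ACGTACGTACGTACGT")
  mk <- function(f, r) list(id = "p1",
                            r1_sequence = pad(full[[f]]),
                            r1_quality = strrep("F", nchar(pad(full[[f]]))),
                            r2_sequence = pad(full[[r]]),
                            r2_quality = strrep("F", nchar(pad(full[[r]]))))

  res <- demux_pair(mk("A", "1"), sheet)
  expect_equal(res$assignment$category, "assigned")
  expect_equal(res$assignment$sample, "S01")
  # tag A and tag 1 are both 5 nt: exactly 5 bases trimmed per mate
  expect_equal(nchar(res$pair$r1_sequence),
               nchar(pad(full[["A"]])) - 5L)
  expect_equal(nchar(res$pair$r2_sequence),
               nchar(pad(full[["1"]])) - 5L)
  expect_equal(nchar(res$pair$r1_quality), nchar(res$pair$r1_sequence))

  off <- demux_pair(mk("A", "2"), sheet)
  expect_equal(off$assignment$category, "unexpected_combination")
  expect_true(is.na(off$assignment$sample))

  bad <- mk("A", "1")
  bad$r1_quality <- "F"
  expect_error(demux_pair(bad, sheet), "length mismatch")
})

test_that("locus-primer trimming honours IUPAC codes and tolerance", {
  # M matches A: exact under expansion
  tr <- trim_locus_primer("GTGCCAGCAGCCGCGGTAATTTT",
                          "GTGCCAGCMGCCGCGGTAA")
  expect_true(tr$trimmed)
  expect_equal(tr$sequence, "TTTT")

  # one real mismatch within tolerance
  tr1 <- trim_locus_primer("CTGCCAGCAGCCGCGGTAATTTT",
                           "GTGCCAGCMGCCGCGGTAA", max_mismatch = 2)
  expect_true(tr1$trimmed)

  # unrelated sequence unchanged and flagged
  tr2 <- trim_locus_primer("AAAAAAAAAAAAAAAAAAAAAAA",
                           "GTGCCAGCMGCCGCGGTAA")
  expect_false(tr2$trimmed)
  expect_equal(tr2$sequence, "AAAAAAAAAAAAAAAAAAAAAAA")

  # positional-comparison oracle on a vector of variants
  primer <- "GTGCCAGCMGCCGCGGTAA"
  reads <- paste0(substitution_variants("GTGCCAGCA")[1:6],
                  substr(primer, 10, 19), "TTTT")
  tr3 <- trim_locus_primer(reads, primer, max_mismatch = 2)
  expect_true(all(tr3$trimmed))
})

test_that("run_demux conserves every read pair across output categories", {
  set.seed(99)
  sheet <- plate_sample_sheet()
  n <- 400
  full <- tag_sequence(sheet$index_set)
  # fuzz: a mix of valid tags, corrupted tags, and random junk
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(3, 1)
    mk <- function(pool) {
      tag <- sample(unname(full[pool]), 1)
      if (kind == 2) { # corrupt 0-3 bases
        v <- strsplit(tag, "")[[1]]
        k <- sample(0:3, 1)
        if (k > 0) {
          at <- sample(seq_along(v), min(k, length(v)))
          v[at] <- sample(c("A", "C", "G", "T"), length(at), TRUE)
        }
        tag <- paste(v, collapse = "")
      }
      if (kind == 3) tag <- paste(sample(c("A", "C", "G", "T"),
                                         sample(6:12, 1), TRUE),
                                  collapse = "")
      paste0(tag, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                        collapse = ""))
    }
    r1[i] <- mk(forward_tags(sheet$index_set)$label)
    r2[i] <- mk(reverse_tags(sheet$index_set)$label)
  }
  dir <- withr::local_tempdir()
  ids <- sprintf("fz%04d", seq_len(n))
  amplitag:::.write_fastq(ids, r1, strrep("F", nchar(r1)),
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(ids, r2, strrep("F", nchar(r2)),
                          file.path(dir, "r2.fastq"))
  out <- file.path(dir, "out")
  st <- run_demux(file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"),
                  sheet, out)
  expect_equal(st$total, n)
  expect_equal(sum(st$per_sample) + sum(st$categories), n)

  # every input pair appears exactly once across all output FASTQs
  written <- unlist(lapply(st$files[grepl("_R1", st$files)], function(f)
    amplitag:::.read_fastq(f)$id))
  expect_equal(sort(written), sort(ids))
})

test_that("demux output is invariant to input read order", {
  sheet <- plate_sample_sheet(fwd_primer = test_fwd_primer(),
                              rev_primer = test_rev_primer())
  sim <- simulate_reads(sheet, reads_per_sample = 3, read_length = 40,
                        insert_length = 60, error_rate = 0.01, seed = 5)
  dir <- withr::local_tempdir()
  w <- function(ids, s1, q1, s2, q2, stem) {
    amplitag:::.write_fastq(ids, s1, q1, file.path(dir, paste0(stem, "_1.fq")))
    amplitag:::.write_fastq(ids, s2, q2, file.path(dir, paste0(stem, "_2.fq")))
  }
  w(sim$r1$id, sim$r1$seq, sim$r1$qual, sim$r2$seq, sim$r2$qual, "fwd")
  o <- rev(seq_along(sim$r1$id))
  w(sim$r1$id[o], sim$r1$seq[o], sim$r1$qual[o],
    sim$r2$seq[o], sim$r2$qual[o], "rev")
  st1 <- run_demux(file.path(dir, "fwd_1.fq"), file.path(dir, "fwd_2.fq"),
                   sheet, NULL)
  st2 <- run_demux(file.path(dir, "rev_1.fq"), file.path(dir, "rev_2.fq"),
                   sheet, NULL)
  expect_equal(st1$per_sample, st2$per_sample)
  expect_equal(st1$categories, st2$categories)
  expect_equal(st1$pair_matrix, st2$pair_matrix)
})

test_that("empty FASTQ input yields empty, conserved statistics", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "e1.fastq"), file.path(dir, "e2.fastq"))
  st <- run_demux(file.path(dir, "e1.fastq"), file.path(dir, "e2.fastq"),
                  plate_sample_sheet(), file.path(dir, "out"))
  expect_equal(st$total, 0L)
  expect_equal(sum(st$per_sample), 0L)
  expect_equal(sum(st$categories), 0L)
})

test_that("mate desynchronization is fatal and names the record", {
  dir <- withr::local_tempdir()
  amplitag:::.write_fastq(c("a", "b"), c("ACGT", "ACGT"), c("FFFF", "FFFF"),
                          file.path(dir, "r1.fastq"))
  amplitag:::.write_fastq(c("a", "c"), c("ACGT", "ACGT"), c("FFFF", "FFFF"),
                          file.path(dir, "r2.fastq"))
  expect_error(run_demux(file.path(dir, "r1.fastq"),
                         file.path(dir, "r2.fastq"),
                         plate_sample_sheet(), NULL),
               "desynchronization.*record 2")
})

test_that("sample sheets validate their entries", {
  expect_error(sample_sheet(data.frame(sample_id = "S1")), "columns")
  expect_error(sample_sheet(data.frame(sample_id = c("S1", "S1"),
                                       fwd_tag = c("A", "B"),
                                       rev_tag = c("1", "2"))),
               "duplicated sample IDs")
  expect_error(sample_sheet(data.frame(sample_id = c("S1", "S2"),
                                       fwd_tag = c("A", "A"),
                                       rev_tag = c("1", "1"))),
               "duplicated tag combinations")
  expect_error(sample_sheet(data.frame(sample_id = "S1",
                                       fwd_tag = "Z", rev_tag = "1")),
               "absent from index set")
  # round trip through CSV
  sheet <- plate_sample_sheet()
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, path)
  sheet2 <- read_sample_sheet(path)
  expect_equal(sheet2$entries, sheet$entries)
})
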