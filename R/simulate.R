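.BASES <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
}

## draw a concrete realisation of an IUPAC primer for each of n
## molecules (a degenerate position is a synthesis-time base mixture,
## so each molecule carries one concrete base)
.concretize <- function(primer, n) {
  codes <- strsplit(toupper(primer), "")[[1]]
  m <- matrix("", n, length(codes))
  for (p in seq_along(codes)) {
    allowed <- strsplit(.IUPAC[[codes[p]]], "")[[1]]
    m[, p] <- if (length(allowed) == 1L) allowed
              else sample(allowed, n, replace = TRUE)
  }
  apply(m, 1L, paste, collapse = "")
}

## inject iid substitution errors; returns sequences plus 0-based
## per-read error positions
.inject_errors <- function(seqs, rate) {
  n <- length(seqs)
  pos <- rep(list(integer(0)), n)
  if (rate <= 0 || n == 0L) return(list(seq = seqs, pos = pos))
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE),
                     use.names = FALSE), ncol = L, byrow = TRUE)
  hit <- matrix(stats::runif(n * L) < rate, n, L)
  idx <- which(hit)
  if (length(idx)) {
    m[idx] <- vapply(m[idx],
                     function(b) sample(setdiff(.BASES, b), 1L),
                     character(1L))
    seqs <- apply(m, 1L, paste, collapse = "")
    rows <- ((idx - 1L) %% n) + 1L
    cols <- ((idx - 1L) %/% n) + 1L
    for (k in seq_along(idx))
      pos[[rows[k]]] <- c(pos[[rows[k]]], cols[k] - 1L)
    pos <- lapply(pos, sort)
  }
  list(seq = seqs, pos = pos)
}

#' Simulate paired-end reads from inline-tagged amplicon libraries
#'
#' Generates the reads an Illumina instrument would produce from
#' full-length quadruple-indexed amplicon constructs with known sample
#' of origin.  The top strand of a construct is
#' P5 + i5 + Read1 + (fwd spacer+index) + fwd primer + insert +
#' revcomp(rev primer) + revcomp(rev index+spacer) + revcomp(Read2) +
#' i7 + P7.  Read 1 starts at the base after the Read1 site, so it
#' begins with the forward tag; Read 2 starts after the Read2 site on
#' the bottom strand, so it begins with the reverse tag (spacer first),
#' then the reverse locus primer, then the reverse-complemented insert.
#' Reads extending past the insert run into the opposite primer, tag
#' and adapter tail, as on the instrument.
#'
#' Outer i5/i7 indexes are emitted as FASTQ header comments
#' (`i5=.. i7=..`) rather than simulated basecalls, matching the
#' assumption that outer demultiplexing has already happened.
#' Substitution errors are injected independently per base; the error
#' model is substitution-only with constant quality Q37, which is what
#' the Hamming tag matcher assumes.  IUPAC codes in the locus primers
#' are concretised per molecule.  Output is deterministic for a fixed
#' `seed`.
#'
#' @param sheet a [sample_sheet()] whose `fwd_primer`/`rev_primer` are
#'   set (they define the read structure).
#' @param out_dir output directory for the FASTQ pair, truth table TSV
#'   and parameter JSON; `NULL` keeps everything in memory.
#' @param reads_per_sample read pairs per sheet entry (default 50).
#' @param read_length length of each mate (default 150).
#' @param inserts optional character vector of insert sequences
#'   (recycled across reads); default: seeded-random inserts of
#'   `insert_length` bp.
#' @param insert_length length of random inserts (default 150).
#' @param error_rate per-base substitution probability in `[0, 0.5)`.
#' @param tag_jump_rate probability that a pair's Read-2 tag is swapped
#'   for a different reverse tag, emulating chimeric "tag jumping"
#'   (default 0).
#' @param chemistry `"truseq"` or `"nextera"` (sets the adapter tails
#'   seen on read-through).
#' @param seed integer seed.
#' @param compress gzip the FASTQ output.
#' @return An object of class `sim_library`: list with `r1`, `r2`
#'   (in-memory reads: `id`, `seq`, `qual`), `truth` (data frame: read
#'   id, sample, embedded tags, tag-jump flag, 0-based half-open insert
#'   coordinates on Read 1, 0-based injected error positions), `params`,
#'   and file paths when `out_dir` is given.
#' @examples
#' sheet <- plate_sample_sheet(
#'   fwd_primer = "AAAAAAGTCAGGTCAAGG",
#'   rev_primer = "GGTGACGGGCGGTGTGTG")
#' sim <- simulate_reads(sheet, reads_per_sample = 2, seed = 1)
#' nrow(sim$truth)   # 192
#' @export
simulate_reads <- function(sheet, out_dir = NULL,
                           reads_per_sample = 50, read_length = 150,
                           inserts = NULL, insert_length = 150,
                           error_rate = 0, tag_jump_rate = 0,
                           chemistry = c("truseq", "nextera"),
                           seed = 1, compress = TRUE) {
  chemistry <- match.arg(chemistry)
  stopifnot(inherits(sheet, "sample_sheet"))
  if (nrow(sheet$entries) == 0L) stop("empty sample sheet")
  if (is.null(sheet$fwd_primer) || is.null(sheet$rev_primer))
    stop("the sheet needs fwd_primer and rev_primer to define the ",
         "read structure")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  set.seed(seed)

  entries <- sheet$entries
  n <- nrow(entries) * reads_per_sample
  ei <- rep(seq_len(nrow(entries)), each = reads_per_sample)

  fseq <- tag_sequence(forward_tags(sheet$index_set))
  rseq <- tag_sequence(reverse_tags(sheet$index_set))
  fwd_full <- unname(fseq[entries$fwd_tag[ei]])
  rev_lab <- entries$rev_tag[ei]

  longest_tag <- max(nchar(c(fseq, rseq)))
  min_rl <- longest_tag +
    max(nchar(sheet$fwd_primer$sequence),
        nchar(sheet$rev_primer$sequence)) + 1L
  if (read_length < min_rl)
    stop("read_length must be at least ", min_rl,
         " (longest tag + locus primer + 1)")

  ## tag jumping: swap the Read-2 tag for a different reverse tag
  jumped <- tag_jump_rate > 0 & stats::runif(n) < tag_jump_rate
  if (any(jumped)) {
    others <- vapply(rev_lab[jumped], function(l)
      sample(setdiff(names(rseq), l), 1L), character(1L))
    rev_lab[jumped] <- others
  }
  rev_full <- unname(rseq[rev_lab])

  fwdP <- .concretize(sheet$fwd_primer$sequence, n)
  revP <- .concretize(sheet$rev_primer$sequence, n)
  ins <- if (is.null(inserts)) {
    if (insert_length < 1L) stop("insert_length must be >= 1")
    apply(matrix(sample(.BASES, n * insert_length, replace = TRUE),
                 n), 1L, paste, collapse = "")
  } else rep_len(toupper(inserts), n)

  tails <- adapter_tails(chemistry)
  r1 <- paste0(fwd_full, fwdP, ins, .revcomp(revP), .revcomp(rev_full),
               .revcomp(tails[2L]))
  r2 <- paste0(rev_full, revP, .revcomp(ins), .revcomp(fwdP),
               .revcomp(fwd_full), .revcomp(tails[1L]))
  short <- nchar(r1) < read_length | nchar(r2) < read_length
  if (any(short))
    stop("template shorter than read_length for ", sum(short),
         " read(s); use longer inserts or a shorter read_length")
  r1 <- substr(r1, 1L, read_length)
  r2 <- substr(r2, 1L, read_length)

  e1 <- .inject_errors(r1, error_rate)
  e2 <- .inject_errors(r2, error_rate)

  id <- sprintf("sim%06d", seq_len(n))
  header <- id
  if (all(c("i5", "i7") %in% names(entries)))
    header <- paste0(id, " i5=", entries$i5[ei],
                     " i7=", entries$i7[ei])
  qual <- strrep(rawToChar(as.raw(33L + 37L)), read_length)

  ins_start <- nchar(fwd_full) + nchar(fwdP)
  truth <- data.frame(
    id = id, sample_id = entries$sample_id[ei],
    fwd_tag = entries$fwd_tag[ei], rev_tag = rev_lab,
    expected_rev_tag = entries$rev_tag[ei], tag_jumped = jumped,
    r1_insert_start = ins_start,
    r1_insert_end = pmin(read_length, ins_start + nchar(ins)),
    r1_errors = vapply(e1$pos, paste, character(1L), collapse = ";"),
    r2_errors = vapply(e2$pos, paste, character(1L), collapse = ";"),
    stringsAsFactors = FALSE)

  params <- list(samples = nrow(entries),
                 reads_per_sample = reads_per_sample,
                 read_length = read_length,
                 insert_length = if (is.null(inserts)) insert_length
                                 else NA,
                 error_rate = error_rate,
                 tag_jump_rate = tag_jump_rate,
                 chemistry = chemistry, seed = seed)

  out <- list(r1 = list(id = header, seq = e1$seq,
                        qual = rep(qual, n)),
              r2 = list(id = header, seq = e2$seq,
                        qual = rep(qual, n)),
              truth = truth, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (compress) ".fastq.gz" else ".fastq"
    out$r1_path <- file.path(out_dir, paste0("reads_R1", ext))
    out$r2_path <- file.path(out_dir, paste0("reads_R2", ext))
    .write_fastq(out$r1$id, out$r1$seq, out$r1$qual, out$r1_path,
                 compress)
    .write_fastq(out$r2$id, out$r2$seq, out$r2$qual, out$r2_path,
                 compress)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(out, class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Simulated library: %d samples x %d pairs, ",
                     "read length %d, error rate %g\n"),
              p$samples, p$reads_per_sample, p$read_length,
              p$error_rate))
  if (!is.null(x$r1_path))
    cat("  files:", x$r1_path, x$r2_path, "\n")
  invisible(x)
}

#' Score demultiplexing output against simulation ground truth
#'
#' @param x a `demux_stats` result (from [run_demux()]) or a data frame
#'   of per-read assignments with columns `id`, `sample`, `category`.
#' @param truth the `truth` table of a [simulate_reads()] result.
#' @return An object of class `demux_score`: counts and fractions
#'   `correct`, `misassigned`, `unassigned` (the three fractions sum
#'   to 1), plus `n`.
#' @examples
#' \dontrun{
#' score_demux(run_demux(sim$r1_path, sim$r2_path, sheet, NULL),
#'             sim$truth)
#' }
#' @export
score_demux <- function(x, truth) {
  a <- if (inherits(x, "demux_stats")) x$assignments else x
  stopifnot(is.data.frame(a),
            all(c("id", "sample", "category") %in% names(a)))
  if (nrow(a) != nrow(truth) || !setequal(a$id, truth$id))
    stop("assignment and truth read-ID universes differ")
  a <- a[match(truth$id, a$id), , drop = FALSE]
  assigned <- a$category == "assigned"
  correct <- assigned & a$sample == truth$sample_id
  correct[is.na(correct)] <- FALSE
  mis <- assigned & !correct
  n <- nrow(truth)
  structure(list(n = n,
                 n_correct = sum(correct),
                 n_misassigned = sum(mis),
                 n_unassigned = sum(!assigned),
                 fraction_correct = sum(correct) / n,
                 fraction_misassigned = sum(mis) / n,
                 fraction_unassigned = sum(!assigned) / n),
            class = "demux_score")
}

#' @export
print.demux_score <- function(x, ...) {
  cat(sprintf("Demux accuracy over %d read pairs:\n", x$n))
  cat(sprintf("  correct:     %d (%.2f%%)\n", x$n_correct,
              100 * x$fraction_correct))
  cat(sprintf("  misassigned: %d (%.2f%%)\n", x$n_misassigned,
              100 * x$fraction_misassigned))
  cat(sprintf("  unassigned:  %d (%.2f%%)\n", x$n_unassigned,
              100 * x$fraction_unassigned))
  invisible(x)
}
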