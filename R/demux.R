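#' Build a sample sheet for inline-tag demultiplexing
#'
#' A sample sheet maps (forward tag, reverse tag) combinations to sample
#' IDs for one sequencing pool.  Outer i5/i7 index labels may be carried
#' per entry (outer demultiplexing is assumed to have happened already;
#' the labels are only used for optional header-comment filtering).
#' Locus primers may be attached so demultiplexing can also trim them.
#'
#' @param entries data frame with columns `sample_id`, `fwd_tag`,
#'   `rev_tag` and optionally `i5`, `i7`.
#' @param index_set the [index_set()] the tag labels refer to.
#' @param fwd_primer,rev_primer optional [locus_primer()] objects (or
#'   plain IUPAC sequences) for primer trimming and read simulation.
#' @param name sheet name.
#' @return An object of class `sample_sheet`.
#' @seealso [plate_sample_sheet()], [read_sample_sheet()], [run_demux()]
#' @export
sample_sheet <- function(entries, index_set = default_index_set(),
                         fwd_primer = NULL, rev_primer = NULL,
                         name = "sample_sheet") {
  need <- c("sample_id", "fwd_tag", "rev_tag")
  if (!all(need %in% names(entries)))
    stop("entries must have columns ", paste(need, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  for (col in need) entries[[col]] <- as.character(entries[[col]])
  if (anyDuplicated(entries$sample_id))
    stop("duplicated sample IDs")
  key <- paste(entries$fwd_tag, entries$rev_tag)
  if (anyDuplicated(key))
    stop("duplicated tag combinations: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  bad_f <- setdiff(entries$fwd_tag, forward_tags(index_set)$label)
  bad_r <- setdiff(entries$rev_tag, reverse_tags(index_set)$label)
  if (length(bad_f) || length(bad_r))
    stop("tag labels absent from index set: ",
         paste(c(bad_f, bad_r), collapse = ", "))
  as_primer <- function(p, orientation) {
    if (is.null(p) || inherits(p, "locus_primer")) p
    else locus_primer(paste0(orientation, "_primer"), p, orientation)
  }
  structure(list(entries = entries, index_set = index_set,
                 fwd_primer = as_primer(fwd_primer, "forward"),
                 rev_primer = as_primer(rev_primer, "reverse"),
                 name = name),
            class = "sample_sheet")
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("Sample sheet '%s': %d samples over index set '%s'\n",
              x$name, nrow(x$entries), attr(x$index_set, "name")))
  if (!is.null(x$fwd_primer))
    cat("  fwd primer:", x$fwd_primer$sequence, "\n")
  if (!is.null(x$rev_primer))
    cat("  rev primer:", x$rev_primer$sequence, "\n")
  print(utils::head(x$entries, 12L), ...)
  if (nrow(x$entries) > 12L) cat("  ...\n")
  invisible(x)
}

#' Full-plate combinatorial sample sheet
#'
#' Convenience constructor for the standard 96-well layout: wells are
#' enumerated row-major (A1, A2, .., H12), well (r, c) receiving forward
#' tag r and reverse tag c.
#'
#' @param sample_ids 96 sample IDs in well order (default "S01".."S96").
#' @inheritParams sample_sheet
#' @return A [sample_sheet()] with 96 entries.
#' @export
plate_sample_sheet <- function(sample_ids = sprintf("S%02d", 1:96),
                               index_set = default_index_set(),
                               fwd_primer = NULL, rev_primer = NULL) {
  fwd <- forward_tags(index_set)$label
  rev <- reverse_tags(index_set)$label
  if (length(fwd) != 8L || length(rev) != 12L)
    stop("a 96-well plate sheet needs 8 forward and 12 reverse tags")
  if (length(sample_ids) != 96L) stop("need exactly 96 sample IDs")
  entries <- data.frame(
    sample_id = sample_ids,
    fwd_tag = rep(fwd, each = 12L),
    rev_tag = rep(rev, times = 8L),
    stringsAsFactors = FALSE)
  sample_sheet(entries, index_set, fwd_primer, rev_primer,
               name = "plate96")
}

#' Read / write a sample sheet as CSV
#'
#' @param path CSV with columns `sample_id`, `fwd_tag`, `rev_tag` and
#'   optionally `i5`, `i7`.
#' @inheritParams sample_sheet
#' @return `read_sample_sheet()` returns a [sample_sheet()];
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path, index_set = default_index_set(),
                              fwd_primer = NULL, rev_primer = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  sample_sheet(df, index_set, fwd_primer, rev_primer,
               name = basename(path))
}

#' @param sheet a [sample_sheet()].
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Hamming distances from each string (>= L chars) to one target of
## length L, comparing the first L characters.
.hamming_vs <- function(strings, target) {
  L <- nchar(target)
  if (length(strings) == 0L) return(integer(0))
  sm <- matrix(unlist(strsplit(strings, "", fixed = TRUE),
                      use.names = FALSE),
               ncol = L, byrow = TRUE)
  tm <- matrix(strsplit(target, "")[[1]], nrow(sm), L, byrow = TRUE)
  as.integer(rowSums(sm != tm))
}

#' Match a read prefix against candidate inline tags
#'
#' Each candidate's full sequence (spacer + index) is compared by
#' Hamming distance against the equal-length prefix of the read:
#' variable tag lengths are handled by testing every candidate at its
#' own length, not by first guessing the spacer length.  A read matches
#' the unique candidate within `max_dist`; if two or more candidates
#' (possibly of different lengths) tie at the minimum qualifying
#' distance the read is ambiguous and left unmatched.  Hamming rather
#' than Levenshtein distance is used because indels in the first few
#' sequencing cycles are rare and indel-tolerant matching is ill-posed
#' across a length-staggered tag set.
#'
#' With the default set's minimum pairwise edit distance of 3,
#' `max_dist = 1` can never convert one tag into another, so
#' single-error reads are recovered without risk of misassignment.
#'
#' @param read_prefix character vector of read 5' prefixes (full reads
#'   are fine).
#' @param candidates an [index_set()] (typically [forward_tags()] or
#'   [reverse_tags()] of the sheet's set).
#' @param max_dist maximum Hamming distance accepted (default 1).
#' @return Data frame with one row per read: `label` (matched tag label
#'   or `NA`), `distance`, and `status` (`"matched"`, `"ambiguous"`, or
#'   `"no_tag"`).
#' @examples
#' match_tag("GGTACAAAAAAGTCAGG", forward_tags(default_index_set()))
#' @export
match_tag <- function(read_prefix, candidates, max_dist = 1) {
  full <- unname(tag_sequence(candidates))
  if (length(full) == 0L) stop("no candidate tags")
  nr <- length(read_prefix)
  if (nr == 0L)
    return(data.frame(label = character(0), distance = numeric(0),
                      status = character(0)))
  rp <- toupper(read_prefix)
  rl <- nchar(rp)
  D <- matrix(Inf, nr, length(full))
  for (j in seq_along(full)) {
    L <- nchar(full[j])
    ok <- rl >= L
    if (any(ok))
      D[ok, j] <- .hamming_vs(substr(rp[ok], 1L, L), full[j])
  }
  mind <- apply(D, 1L, min)
  nmin <- rowSums(D == mind)
  hit <- is.finite(mind) & mind <= max_dist
  matched <- hit & nmin == 1L
  label <- rep(NA_character_, nr)
  if (any(matched))
    label[matched] <- candidates$label[
      apply(D[matched, , drop = FALSE], 1L, which.min)]
  status <- ifelse(matched, "matched",
                   ifelse(hit, "ambiguous", "no_tag"))
  data.frame(label = label,
             distance = ifelse(matched, mind, NA_real_),
             status = status, stringsAsFactors = FALSE)
}

## vectorised core: assign read pairs to samples / categories
.assign_pairs <- function(r1, r2, sheet, max_dist = 1) {
  fm <- match_tag(r1, forward_tags(sheet$index_set), max_dist)
  rm_ <- match_tag(r2, reverse_tags(sheet$index_set), max_dist)
  key <- paste(fm$label, rm_$label, sep = "\r")
  skey <- paste(sheet$entries$fwd_tag, sheet$entries$rev_tag, sep = "\r")
  sample <- sheet$entries$sample_id[match(key, skey)]
  both <- fm$status == "matched" & rm_$status == "matched"
  category <- ifelse(both & !is.na(sample), "assigned",
              ifelse(both, "unexpected_combination",
              ifelse(fm$status == "ambiguous" | rm_$status == "ambiguous",
                     "unassigned_ambiguous", "unassigned_no_tag")))
  sample[category != "assigned"] <- NA_character_
  fseq <- tag_sequence(forward_tags(sheet$index_set))
  rseq <- tag_sequence(reverse_tags(sheet$index_set))
  data.frame(sample = sample, category = category,
             fwd_tag = fm$label, rev_tag = rm_$label,
             fwd_dist = fm$distance, rev_dist = rm_$distance,
             trim1 = ifelse(fm$status == "matched",
                            nchar(fseq[fm$label]), 0L),
             trim2 = ifelse(rm_$status == "matched",
                            nchar(rseq[rm_$label]), 0L),
             stringsAsFactors = FALSE)
}

#' Demultiplex a single read pair
#'
#' Matches the forward tags against the Read 1 prefix and the reverse
#' tags against the Read 2 prefix.  When both tags match and the
#' combination is on the sheet the pair is assigned to that sample and
#' the tag bases (spacer + index) are trimmed from the 5' end of each
#' mate, qualities in lockstep.  A pair whose tags both match but whose
#' combination is absent from the sheet is an `unexpected_combination`
#' (a candidate tag jump); otherwise the pair falls into
#' `unassigned_ambiguous` or `unassigned_no_tag`.
#'
#' @param pair list with elements `id`, `r1_sequence`, `r1_quality`,
#'   `r2_sequence`, `r2_quality`.
#' @param sheet a [sample_sheet()].
#' @param max_dist per-tag Hamming tolerance (default 1).
#' @param trim_primers also trim the sheet's locus primers after the
#'   tag (see [trim_locus_primer()]).
#' @param primer_max_mismatch mismatch tolerance for primer trimming.
#' @return List with `assignment` (one-row data frame: `sample`,
#'   `category`, matched tags, distances) and `pair` (the trimmed pair).
#' @export
demux_pair <- function(pair, sheet, max_dist = 1, trim_primers = FALSE,
                       primer_max_mismatch = 2) {
  stopifnot(is.list(pair))
  if (nchar(pair$r1_sequence) != nchar(pair$r1_quality) ||
      nchar(pair$r2_sequence) != nchar(pair$r2_quality))
    stop("malformed pair '", pair$id,
         "': sequence/quality length mismatch")
  a <- .assign_pairs(pair$r1_sequence, pair$r2_sequence, sheet,
                     max_dist)
  t1 <- a$trim1; t2 <- a$trim2
  r1 <- substring(pair$r1_sequence, t1 + 1L)
  q1 <- substring(pair$r1_quality, t1 + 1L)
  r2 <- substring(pair$r2_sequence, t2 + 1L)
  q2 <- substring(pair$r2_quality, t2 + 1L)
  if (trim_primers && a$category == "assigned") {
    if (!is.null(sheet$fwd_primer)) {
      tr <- .primer_trim_len(r1, sheet$fwd_primer$sequence,
                             primer_max_mismatch)
      r1 <- substring(r1, tr + 1L); q1 <- substring(q1, tr + 1L)
    }
    if (!is.null(sheet$rev_primer)) {
      tr <- .primer_trim_len(r2, sheet$rev_primer$sequence,
                             primer_max_mismatch)
      r2 <- substring(r2, tr + 1L); q2 <- substring(q2, tr + 1L)
    }
  }
  list(assignment = a,
       pair = list(id = pair$id, r1_sequence = r1, r1_quality = q1,
                   r2_sequence = r2, r2_quality = q2))
}

## IUPAC-aware mismatch counts of a primer against read starts;
## returns Inf where the read is shorter than the primer
.iupac_mismatches <- function(reads, primer) {
  L <- nchar(primer)
  n <- length(reads)
  out <- rep(Inf, n)
  ok <- nchar(reads) >= L
  if (!any(ok)) return(out)
  sm <- matrix(unlist(strsplit(substr(reads[ok], 1L, L), "",
                               fixed = TRUE), use.names = FALSE),
               ncol = L, byrow = TRUE)
  codes <- strsplit(toupper(primer), "")[[1]]
  mism <- matrix(FALSE, nrow(sm), L)
  for (p in seq_len(L)) {
    allowed <- strsplit(.IUPAC[[codes[p]]], "")[[1]]
    mism[, p] <- !(sm[, p] %in% allowed)
  }
  out[ok] <- rowSums(mism)
  out
}

.primer_trim_len <- function(reads, primer, max_mismatch = 2) {
  mm <- .iupac_mismatches(toupper(reads), primer)
  ifelse(mm <= max_mismatch, nchar(primer), 0L)
}

#' Trim a locus primer from sequence starts
#'
#' Compares the IUPAC-expanded primer against the start of each
#' sequence (a degenerate code matches any base it stands for).  Where
#' at most `max_mismatch` positions disagree the primer is removed;
#' otherwise the sequence is returned unchanged and flagged.
#'
#' @param sequence character vector of sequences.
#' @param primer a single IUPAC primer sequence.
#' @param max_mismatch mismatch tolerance (default 2).
#' @return Data frame with columns `sequence` (possibly trimmed) and
#'   `trimmed` (logical flag).
#' @examples
#' trim_locus_primer("GTGCCAGCAGCCGCGGTAATT", "GTGCCAGCMGCCGCGGTAA")
#' @export
trim_locus_primer <- function(sequence, primer, max_mismatch = 2) {
  if (!nzchar(primer)) stop("empty primer")
  tr <- .primer_trim_len(sequence, primer, max_mismatch)
  data.frame(sequence = substring(sequence, tr + 1L),
             trimmed = tr > 0L, stringsAsFactors = FALSE)
}

#' Demultiplex paired-end FASTQ by inline tags
#'
#' Streams a paired FASTQ file set (plain or gzip) through the tag
#' matcher, writes one FASTQ pair per sample plus per-category
#' unassigned files, and reports statistics including the full observed
#' tag-combination matrix.  Unexpected combinations (both tags match but
#' the pair is not on the sheet, e.g. from chimeric "tag jumping") are
#' never silently dropped: they are counted, written to their own
#' files, and visible in the matrix.
#'
#' Outer i5/i7 demultiplexing is assumed already done.  If the sheet
#' carries `i5`/`i7` columns and `filter_outer = TRUE`, reads whose
#' FASTQ header comments carry `i5=..`/`i7=..` labels disagreeing with
#' the matched entry are reclassified as unexpected combinations.
#'
#' @param fastq_r1,fastq_r2 paths to the mate FASTQ files (gzip
#'   detected from content).
#' @param sheet a [sample_sheet()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and only returns statistics.
#' @param max_dist per-tag Hamming tolerance (default 1; 0 for exact).
#' @param trim_primers trim the sheet's locus primers after the tag.
#' @param primer_max_mismatch mismatch tolerance for primer trimming.
#' @param min_len pairs with either mate shorter than this after
#'   trimming go to category `too_short` (default 0 = keep all).
#' @param filter_outer check header i5/i7 labels against the sheet.
#' @param compress gzip the output FASTQ files.
#' @return An object of class `demux_stats`: total pair count,
#'   per-sample counts, per-category counts, the observed tag-pair
#'   matrix, per-read assignments, and paths of files written.  The
#'   conservation invariant (samples + categories == total) is checked
#'   before returning.  A TSV of per-sample counts and a JSON report
#'   are written alongside the FASTQ output.
#' @examples
#' \dontrun{
#' st <- run_demux("R1.fastq.gz", "R2.fastq.gz",
#'                 plate_sample_sheet(), "demux_out")
#' }
#' @export
run_demux <- function(fastq_r1, fastq_r2, sheet, out_dir = NULL,
                      max_dist = 1, trim_primers = FALSE,
                      primer_max_mismatch = 2, min_len = 0,
                      filter_outer = FALSE, compress = TRUE) {
  stopifnot(inherits(sheet, "sample_sheet"))
  f1 <- .read_fastq(fastq_r1)
  f2 <- .read_fastq(fastq_r2)
  if (length(f1$seq) != length(f2$seq))
    stop("R1 and R2 have different record counts (",
         length(f1$seq), " vs ", length(f2$seq), ")")
  n <- length(f1$seq)
  if (n > 0L) {
    k1 <- .read_key(f1$id); k2 <- .read_key(f2$id)
    bad <- which(k1 != k2)
    if (length(bad))
      stop("mate desynchronization at record ", bad[1L], ": '",
           k1[bad[1L]], "' vs '", k2[bad[1L]], "'")
  }

  if (n > 0L) {
    a <- .assign_pairs(f1$seq, f2$seq, sheet, max_dist)
  } else {
    a <- data.frame(sample = character(0), category = character(0),
                    fwd_tag = character(0), rev_tag = character(0),
                    fwd_dist = numeric(0), rev_dist = numeric(0),
                    trim1 = integer(0), trim2 = integer(0))
  }

  if (filter_outer && n > 0L &&
      all(c("i5", "i7") %in% names(sheet$entries))) {
    obs_i5 <- .header_field(f1$id, "i5")
    obs_i7 <- .header_field(f1$id, "i7")
    idx <- match(a$sample, sheet$entries$sample_id)
    mismatch <- a$category == "assigned" &
      ((!is.na(obs_i5) & obs_i5 != sheet$entries$i5[idx]) |
       (!is.na(obs_i7) & obs_i7 != sheet$entries$i7[idx]))
    a$category[mismatch] <- "unexpected_combination"
    a$sample[mismatch] <- NA_character_
  }

  ## trim tags (and optionally primers) with qualities in lockstep
  s1 <- substring(f1$seq, a$trim1 + 1L)
  q1 <- substring(f1$qual, a$trim1 + 1L)
  s2 <- substring(f2$seq, a$trim2 + 1L)
  q2 <- substring(f2$qual, a$trim2 + 1L)
  if (trim_primers && n > 0L) {
    assigned <- a$category == "assigned"
    if (!is.null(sheet$fwd_primer) && any(assigned)) {
      tr <- ifelse(assigned,
                   .primer_trim_len(s1, sheet$fwd_primer$sequence,
                                    primer_max_mismatch), 0L)
      s1 <- substring(s1, tr + 1L); q1 <- substring(q1, tr + 1L)
    }
    if (!is.null(sheet$rev_primer) && any(assigned)) {
      tr <- ifelse(assigned,
                   .primer_trim_len(s2, sheet$rev_primer$sequence,
                                    primer_max_mismatch), 0L)
      s2 <- substring(s2, tr + 1L); q2 <- substring(q2, tr + 1L)
    }
  }
  if (min_len > 0 && n > 0L) {
    short <- a$category == "assigned" &
      (nchar(s1) < min_len | nchar(s2) < min_len)
    a$category[short] <- "too_short"
    a$sample[short] <- NA_character_
  }

  per_sample <- setNames(integer(nrow(sheet$entries)),
                         sheet$entries$sample_id)
  tab <- table(a$sample[a$category == "assigned"])
  per_sample[names(tab)] <- as.integer(tab)
  cats <- c("unassigned_no_tag", "unassigned_ambiguous",
            "unexpected_combination", "too_short")
  categories <- setNames(integer(length(cats)), cats)
  ctab <- table(a$category[a$category != "assigned"])
  categories[names(ctab)] <- as.integer(ctab)

  fwd_labels <- forward_tags(sheet$index_set)$label
  rev_labels <- reverse_tags(sheet$index_set)$label
  pair_matrix <- matrix(0L, length(fwd_labels), length(rev_labels),
                        dimnames = list(fwd_labels, rev_labels))
  seen <- !is.na(a$fwd_tag) & !is.na(a$rev_tag)
  if (any(seen)) {
    pt <- table(factor(a$fwd_tag[seen], levels = fwd_labels),
                factor(a$rev_tag[seen], levels = rev_labels))
    pair_matrix[] <- as.integer(pt)
  }

  if (sum(per_sample) + sum(categories) != n)
    stop("internal error: read conservation violated")

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (compress) ".fastq.gz" else ".fastq"
    emit <- function(idx, stem) {
      p1 <- file.path(out_dir, paste0(stem, "_R1", ext))
      p2 <- file.path(out_dir, paste0(stem, "_R2", ext))
      .write_fastq(f1$id[idx], s1[idx], q1[idx], p1, compress)
      .write_fastq(f2$id[idx], s2[idx], q2[idx], p2, compress)
      c(p1, p2)
    }
    for (s in sheet$entries$sample_id) {
      idx <- which(a$category == "assigned" & a$sample == s)
      if (length(idx))
        files <- c(files, emit(idx, .safe_name(s)))
    }
    for (cat_ in cats) {
      idx <- which(a$category == cat_)
      if (length(idx))
        files <- c(files, emit(idx, paste0("unassigned_", cat_)))
    }
  }

  stats <- structure(
    list(total = n, per_sample = per_sample, categories = categories,
         pair_matrix = pair_matrix,
         assignments = data.frame(id = if (n) .read_key(f1$id)
                                       else character(0),
                                  a, stringsAsFactors = FALSE),
         files = files, max_dist = max_dist),
    class = "demux_stats")

  if (!is.null(out_dir)) {
    counts <- data.frame(sample = names(per_sample),
                         reads = as.integer(per_sample))
    write.table(counts, file.path(out_dir, "demux_counts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(total = n, per_sample = as.list(per_sample),
           categories = as.list(categories),
           pair_matrix = as.data.frame(pair_matrix)),
      file.path(out_dir, "demux_stats.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  stats
}

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

.header_field <- function(id, field) {
  pat <- paste0(".*[ \t]", field, "=([^ \t]+).*")
  out <- rep(NA_character_, length(id))
  has <- grepl(paste0("[ \t]", field, "="), id)
  out[has] <- sub(pat, "\\1", id[has])
  out
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("Demultiplexed %d read pairs (max_dist = %d)\n",
              x$total, x$max_dist))
  cat(sprintf("  assigned: %d over %d samples\n",
              sum(x$per_sample), sum(x$per_sample > 0L)))
  for (k in names(x$categories))
    if (x$categories[[k]] > 0L)
      cat(sprintf("  %s: %d\n", k, x$categories[[k]]))
  jumps <- x$categories[["unexpected_combination"]]
  if (!is.na(jumps) && jumps > 0L)
    cat("  (unexpected combinations may indicate tag jumping)\n")
  invisible(x)
}
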