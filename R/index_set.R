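#' Construct an internal index set
#'
#' An index set is the collection of inline tags used to identify samples
#' within a pooled amplicon library.  Each tag is a short heterogeneity
#' spacer (possibly empty, stored lowercase) followed by a fixed-length
#' identifying index (stored uppercase).  Forward tags are read as the
#' first bases of Read 1, reverse tags as the first bases of Read 2, so
#' the spacer staggers otherwise phase-identical amplicons across
#' sequencing cycles.
#'
#' Tags are grouped into tetrads (groups of four) whose full sequences
#' have staggered lengths and whose bases are balanced between the two
#' detection channels of four-colour Illumina instruments (A/C red,
#' G/T green) at every shared cycle.
#'
#' @param label character vector of tag labels (conventionally "A".."H"
#'   for forward tags and "1".."12" for reverse tags).
#' @param role character vector, each element `"forward"` or `"reverse"`.
#' @param spacer character vector of heterogeneity spacers over A/C/G/T
#'   (case-insensitive; may be empty strings).
#' @param index character vector of identifying indexes over A/C/G/T,
#'   all of one common length (5 nt in the default design).
#' @param group integer vector of tetrad memberships.
#' @param name optional name for the set.
#' @return An object of class `index_set`: a data frame with columns
#'   `label`, `role`, `spacer`, `index`, `group` (spacer lowercase,
#'   index uppercase).
#' @seealso [default_index_set()], [validate_index_set()],
#'   [design_index_set()]
#' @examples
#' index_set(label = c("A", "B"), role = c("forward", "reverse"),
#'           spacer = c("", "c"), index = c("GGTAC", "AACAC"),
#'           group = c(1, 1))
#' @export
index_set <- function(label, role, spacer, index, group,
                      name = "index_set") {
  n <- length(label)
  stopifnot(length(role) == n, length(spacer) == n,
            length(index) == n, length(group) == n)
  role <- match.arg(tolower(role), c("forward", "reverse"),
                    several.ok = TRUE)
  spacer <- tolower(spacer)
  index <- toupper(index)
  bad <- grepl("[^acgt]", spacer) | grepl("[^ACGT]", index)
  if (any(bad))
    stop("spacer/index sequences must be plain A/C/G/T: ",
         paste(label[bad], collapse = ", "))
  if (length(unique(nchar(index))) > 1L)
    stop("all indexes in a set must share one length")
  for (r in unique(role)) {
    lab <- label[role == r]
    if (anyDuplicated(lab))
      stop("duplicated ", r, " tag labels: ",
           paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  out <- data.frame(label = as.character(label), role = role,
                    spacer = spacer, index = index,
                    group = as.integer(group),
                    stringsAsFactors = FALSE)
  structure(out, name = name, class = c("index_set", "data.frame"))
}

#' The default 8 + 12 internal index set
#'
#' Returns the packaged default set of 20 inline tags: 8 forward tags
#' ("A".."H") and 12 reverse tags ("1".."12"), each a 0-3 nt
#' heterogeneity spacer plus a 5-nt index.  The set is organised in five
#' tetrads with full-sequence lengths {5,6,7,8}, has minimum pairwise
#' Levenshtein distance 3 between indexes (so a single sequencing error
#' can always be corrected unambiguously), and is red/green
#' channel-balanced at cycles 1-5 within every tetrad.
#'
#' @return An [index_set()] with 20 rows.
#' @examples
#' s <- default_index_set()
#' tag_sequence(s)[s$label == "A"]
#' @export
default_index_set <- function() {
  path <- system.file("extdata", "index_set_default.csv",
                      package = "amplitag", mustWork = TRUE)
  read_index_set(path, name = "default")
}

#' Read / write an index set as CSV
#'
#' The CSV carries one row per tag with columns `label`, `role`,
#' `spacer`, `index`, `group`.  Empty spacers may be blank or `NA`.
#'
#' @param path file path.
#' @param name name to attach to the set.
#' @return `read_index_set()` returns an [index_set()];
#'   `write_index_set()` returns `path` invisibly.
#' @export
read_index_set <- function(path, name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(label = "character",
                                spacer = "character"))
  df$spacer[is.na(df$spacer)] <- ""
  index_set(df$label, df$role, df$spacer, df$index, df$group,
            name = name)
}

#' @param set an [index_set()].
#' @rdname read_index_set
#' @export
write_index_set <- function(set, path) {
  write.csv(as.data.frame(set), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full tag sequences (spacer + index)
#'
#' @param set an [index_set()].
#' @param case `"mixed"` renders the spacer lowercase and the index
#'   uppercase (the human-facing convention); `"upper"` returns the
#'   sequence as it occurs in a read.
#' @return Named character vector (names are tag labels).
#' @export
tag_sequence <- function(set, case = c("upper", "mixed")) {
  case <- match.arg(case)
  s <- paste0(set$spacer, set$index)
  if (case == "upper") s <- toupper(s)
  setNames(s, set$label)
}

#' Subset an index set by role
#' @param set an [index_set()].
#' @return An [index_set()] with only the forward (reverse) tags.
#' @export
forward_tags <- function(set) subset_role(set, "forward")

#' @rdname forward_tags
#' @export
reverse_tags <- function(set) subset_role(set, "reverse")

subset_role <- function(set, role) {
  out <- set[set$role == role, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "name") <- paste0(attr(set, "name"), ":", role)
  class(out) <- c("index_set", "data.frame")
  out
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("Index set '%s': %d forward + %d reverse tags\n",
              attr(x, "name"),
              sum(x$role == "forward"), sum(x$role == "reverse")))
  df <- as.data.frame(x)
  df$sequence <- tag_sequence(x, case = "mixed")
  df$length <- nchar(df$sequence)
  print(df[, c("label", "role", "group", "sequence", "length")], ...)
  invisible(x)
}

#' Minimum pairwise edit distance within an index set
#'
#' Computes the minimum Levenshtein distance (unit-cost substitutions,
#' insertions and deletions) over all unordered pairs of tags, pooling
#' forward and reverse tags into one universe (conservative: also guards
#' against forward/reverse confusion).  A minimum distance of 3 or more
#' lets a demultiplexer correct any single error unambiguously.
#'
#' @param set an [index_set()] with at least two tags.
#' @param on `"index"` compares the fixed-length uppercase indexes only
#'   (the design guarantee of the default set); `"full_sequence"`
#'   compares spacer + index.
#' @return Integer scalar, the minimum pairwise distance.
#' @examples
#' min_edit_distance(default_index_set())           # 3
#' min_edit_distance(default_index_set(), "full_sequence")
#' @export
min_edit_distance <- function(set, on = c("index", "full_sequence")) {
  on <- match.arg(on)
  seqs <- if (on == "index") set$index else tag_sequence(set)
  if (length(seqs) < 2L)
    stop("need at least two tags to compute a pairwise distance")
  d <- adist(seqs)
  as.integer(min(d[upper.tri(d)]))
}

## channel map for MiSeq / HiSeq <= 2500 four-colour chemistry
.RED_BASES <- c("A", "C")

#' Detection-channel balance of an index set
#'
#' Four-colour Illumina chemistry images A/C in the red channel and G/T
#' in the green channel; basecalling needs both channels lit at every
#' cycle.  The tag design achieves this within each tetrad: across the
#' four full sequences (spacer + index), aligned at their 5' ends, each
#' of the shared leading positions carries exactly two red and two green
#' bases.  Positions beyond the shortest member of a tetrad are excluded
#' (members run out at different cycles there).
#'
#' @param set an [index_set()].
#' @return A data frame with one row per (group, position): columns
#'   `group`, `position`, `red`, `green`, `balanced`.  Groups that do
#'   not have exactly four members are skipped and recorded in the
#'   `"incomplete_groups"` attribute.
#' @examples
#' cb <- channel_balance(default_index_set())
#' all(cb$red == 2 & cb$green == 2)
#' @export
channel_balance <- function(set) {
  out <- list()
  incomplete <- integer(0)
  for (g in sort(unique(set$group))) {
    seqs <- tag_sequence(set[set$group == g, , drop = FALSE])
    if (length(seqs) != 4L) {
      incomplete <- c(incomplete, g)
      next
    }
    npos <- min(nchar(seqs))
    for (p in seq_len(npos)) {
      b <- substr(seqs, p, p)
      red <- sum(b %in% .RED_BASES)
      out[[length(out) + 1L]] <-
        data.frame(group = g, position = p, red = red,
                   green = 4L - red)
    }
  }
  out <- if (length(out)) do.call(rbind, out)
         else data.frame(group = integer(0), position = integer(0),
                         red = integer(0), green = integer(0))
  out$balanced <- out$red == out$green
  structure(out, incomplete_groups = incomplete)
}

#' Validate an index set against its design guarantees
#'
#' Checks the three guarantees of the tag design: minimum pairwise edit
#' distance (error-correction headroom), per-tetrad length staggering
#' (base diversity across cycles), and per-tetrad red/green channel
#' balance (basecalling on four-colour instruments).  Violations are
#' reported as data, not raised as errors.
#'
#' @param set an [index_set()].
#' @param min_edit required minimum pairwise Levenshtein distance
#'   (default 3).
#' @param on sequence field for the distance check, as in
#'   [min_edit_distance()].
#' @param spacer_lengths the spacer lengths every tetrad must realise
#'   exactly once (default `0:3`, i.e. full-sequence lengths
#'   index length + 0..3).
#' @return An object of class `index_set_validation` with elements
#'   `min_edit_distance`, `balance_violations`, `length_violations`,
#'   `group_violations`, and `passed` (`TRUE` iff all violation tables
#'   are empty and the distance threshold is met).
#' @examples
#' validate_index_set(default_index_set())$passed   # TRUE
#' @export
validate_index_set <- function(set, min_edit = 3,
                               on = c("index", "full_sequence"),
                               spacer_lengths = 0:3) {
  on <- match.arg(on)
  med <- min_edit_distance(set, on = on)

  cb <- channel_balance(set)
  balance_violations <- cb[!cb$balanced, , drop = FALSE]

  ilen <- nchar(set$index[1L])
  want <- sort(ilen + spacer_lengths)
  length_violations <- list()
  group_violations <- data.frame(group = integer(0), n = integer(0))
  for (g in sort(unique(set$group))) {
    members <- set[set$group == g, , drop = FALSE]
    if (nrow(members) != 4L) {
      group_violations <- rbind(group_violations,
                                data.frame(group = g, n = nrow(members)))
      next
    }
    lens <- sort(unname(nchar(tag_sequence(members))))
    if (!identical(lens, as.integer(want)))
      length_violations[[length(length_violations) + 1L]] <-
        data.frame(group = g,
                   lengths = paste(lens, collapse = ","),
                   expected = paste(want, collapse = ","))
  }
  length_violations <- if (length(length_violations))
    do.call(rbind, length_violations)
  else data.frame(group = integer(0), lengths = character(0),
                  expected = character(0))

  passed <- med >= min_edit &&
    nrow(balance_violations) == 0L &&
    nrow(length_violations) == 0L &&
    nrow(group_violations) == 0L

  structure(list(set_name = attr(set, "name"),
                 min_edit_distance = med,
                 min_edit_required = min_edit,
                 distance_on = on,
                 balance_violations = balance_violations,
                 length_violations = length_violations,
                 group_violations = group_violations,
                 passed = passed),
            class = "index_set_validation")
}

#' @export
print.index_set_validation <- function(x, ...) {
  cat(sprintf("Validation of index set '%s': %s\n", x$set_name,
              if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("  min pairwise edit distance (%s): %d (required >= %d)\n",
              x$distance_on, x$min_edit_distance, x$min_edit_required))
  cat(sprintf("  channel-balance violations: %d\n",
              nrow(x$balance_violations)))
  cat(sprintf("  length-stagger violations:  %d\n",
              nrow(x$length_violations)))
  if (nrow(x$group_violations))
    cat(sprintf("  tetrads without 4 members:  %d\n",
                nrow(x$group_violations)))
  invisible(x)
}

#' Design a new constraint-satisfying index set
#'
#' Searches for a fresh tag set with the same guarantees as the default
#' one: tetrads of four tags whose spacer lengths realise each value of
#' `spacer_lengths` once, exact 2-red/2-green channel balance at every
#' shared leading position, and minimum pairwise Levenshtein distance
#' `min_edit` between indexes across the whole set (forward and reverse
#' pooled).
#'
#' The search is greedy-randomised: for each tetrad a channel pattern
#' (which two of the four members are red at each balanced position) and
#' a spacer-length permutation are drawn, members are then sampled one at
#' a time under that pattern and resampled until their index clears the
#' distance constraint against all previously accepted tags.  Exhausting
#' the budget restarts the tetrad with a new pattern; exhausting the
#' tetrad budget fails with the name of the unsatisfied constraint.
#' Results are deterministic for a fixed `seed`.
#'
#' @param n_forward,n_reverse numbers of forward/reverse tags; each must
#'   be a multiple of 4 (tetrads) or 0.
#' @param index_len index length in nt (default 5).
#' @param spacer_lengths the four spacer lengths used within each tetrad
#'   (default `0:3`; e.g. `4:7` extends spacers for repeat-rich loci).
#' @param min_edit minimum pairwise Levenshtein distance between indexes.
#' @param seed integer seed for the randomised search.
#' @param tetrad_tries,member_tries search budget per tetrad / per member.
#' @return A validated [index_set()].
#' @examples
#' s <- design_index_set(4, 0, seed = 7)
#' sort(nchar(tag_sequence(s)))   # 5 6 7 8
#' @export
design_index_set <- function(n_forward = 8, n_reverse = 12,
                             index_len = 5, spacer_lengths = 0:3,
                             min_edit = 3, seed = 1,
                             tetrad_tries = 200, member_tries = 400) {
  if (n_forward %% 4L || n_reverse %% 4L)
    stop("n_forward and n_reverse must be multiples of 4 (tetrads)")
  if (length(spacer_lengths) != 4L || anyDuplicated(spacer_lengths))
    stop("spacer_lengths must be four distinct lengths")
  if (n_forward + n_reverse < 4L)
    stop("need at least one tetrad")
  set.seed(seed)

  n_tetrads <- (n_forward + n_reverse) %/% 4L
  accepted_idx <- character(0)
  rows <- list()
  red <- .RED_BASES; green <- c("G", "T")

  for (t in seq_len(n_tetrads)) {
    done <- FALSE
    for (attempt in seq_len(tetrad_tries)) {
      sp_len <- sample(spacer_lengths)
      full_len <- index_len + sp_len
      n_bal <- min(full_len)    # positions shared by all four members
      ## channel pattern: which 2 of 4 members are red at each position
      pattern <- vapply(seq_len(n_bal), function(p) {
        m <- rep(FALSE, 4L); m[sample.int(4L, 2L)] <- TRUE; m
      }, logical(4L))
      members <- character(0)
      member_idx <- character(0)
      ok <- TRUE
      for (m in seq_len(4L)) {
        found <- FALSE
        for (k in seq_len(member_tries)) {
          bal <- vapply(seq_len(n_bal), function(p)
            sample(if (pattern[m, p]) red else green, 1L), character(1L))
          tail_n <- full_len[m] - n_bal
          tail <- if (tail_n > 0L)
            sample(c(red, green), tail_n, replace = TRUE)
          else character(0)
          full <- paste(c(bal, tail), collapse = "")
          idx <- substr(full, sp_len[m] + 1L, full_len[m])
          cand_vs <- c(accepted_idx, member_idx)
          if (length(cand_vs) == 0L ||
              min(adist(idx, cand_vs)) >= min_edit) {
            members <- c(members, full)
            member_idx <- c(member_idx, idx)
            found <- TRUE
            break
          }
        }
        if (!found) { ok <- FALSE; break }
      }
      if (ok) {
        rows[[t]] <- data.frame(
          spacer = tolower(substr(members, 1L, sp_len)),
          index = member_idx, group = t)
        accepted_idx <- c(accepted_idx, member_idx)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop(sprintf(paste0("index-set search exhausted at tetrad %d: ",
                          "could not satisfy min edit distance %d ",
                          "(index length %d)"), t, min_edit, index_len))
  }

  df <- do.call(rbind, rows)
  role <- rep(c("forward", "reverse"), c(n_forward, n_reverse))
  label <- c(if (n_forward) make_labels(n_forward, "LETTERS"),
             if (n_reverse) as.character(seq_len(n_reverse)))
  out <- index_set(label, role, df$spacer, df$index, df$group,
                   name = sprintf("designed_seed%d", seed))
  out
}

make_labels <- function(n, kind) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else paste0(LETTERS[(seq_len(n) - 1L) %/% 26L + 1L],
              LETTERS[(seq_len(n) - 1L) %% 26L + 1L])
}

#' Combinatorial multiplexing capacity
#'
#' Number of samples distinguishable by combining inner forward/reverse
#' tags with outer i5/i7 indexes: the product of the four counts.  With
#' the default inner set alone, 8 x 12 = 96 samples per plate; adding
#' 384 i5 and 384 i7 outer primers gives 14,155,776 trackable samples.
#'
#' @param n_fwd_inner,n_rev_inner,n_i5,n_i7 positive integer counts of
#'   distinct identifiers at each of the four index positions (use 1 for
#'   an unused position).
#' @return Numeric scalar, the product.
#' @examples
#' multiplex_capacity(8, 12)             # 96
#' multiplex_capacity(8, 12, 8, 12)      # 9216
#' multiplex_capacity(8, 12, 384, 384)   # 14155776
#' @export
multiplex_capacity <- function(n_fwd_inner, n_rev_inner,
                               n_i5 = 1, n_i7 = 1) {
  n <- c(n_fwd_inner, n_rev_inner, n_i5, n_i7)
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stop("all identifier counts must be positive integers")
  prod(as.numeric(n))
}
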