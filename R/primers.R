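## Partial adapter tails fused 5' of the tag + locus primer.  These are
## the Illumina TruSeq / Nextera Read 1 and Read 2 sequencing-primer
## sites; the outer P5+i5 / P7+i7 ends are added later by indexed
## universal primers in a second, limited-cycle PCR.
.ADAPTER_TAILS <- c(
  TruSeq_Read1  = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
  TruSeq_Read2  = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
  Nextera_Read1 = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
  Nextera_Read2 = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG")

.IUPAC <- Biostrings::IUPAC_CODE_MAP

#' Adapter tail sequences
#'
#' @param chemistry `"truseq"` or `"nextera"`; `NULL` returns all four.
#' @return Named character vector of Read1/Read2 partial adapter tails.
#' @examples
#' adapter_tails("truseq")
#' @export
adapter_tails <- function(chemistry = NULL) {
  if (is.null(chemistry)) return(.ADAPTER_TAILS)
  chemistry <- match.arg(tolower(chemistry), c("truseq", "nextera"))
  pre <- if (chemistry == "truseq") "TruSeq" else "Nextera"
  .ADAPTER_TAILS[paste0(pre, c("_Read1", "_Read2"))]
}

#' Define a locus-specific primer
#'
#' @param name primer name (used in fusion-primer names).
#' @param sequence primer sequence; IUPAC degeneracy codes are allowed
#'   and passed through untouched.
#' @param orientation `"forward"` or `"reverse"`.
#' @return An object of class `locus_primer`.
#' @examples
#' locus_primer("515F", "GTGCCAGCMGCCGCGGTAA", "forward")
#' @export
locus_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("locus primer sequence is empty")
  bad <- setdiff(strsplit(sequence, "")[[1]], names(.IUPAC))
  if (length(bad))
    stop("non-IUPAC characters in primer '", name, "': ",
         paste(unique(bad), collapse = ""))
  structure(list(name = name, sequence = sequence,
                 orientation = orientation),
            class = "locus_primer")
}

#' Read locus primers from CSV
#'
#' Expects columns `name`, `sequence`, `orientation`.
#'
#' @param path file path.
#' @return List of [locus_primer()] objects, named by primer name.
#' @export
read_locus_primers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    locus_primer(df$name[i], df$sequence[i], df$orientation[i]))
  setNames(out, df$name)
}

#' Assemble a single fusion primer
#'
#' A fusion primer is the plain concatenation, 5' to 3', of a partial
#' adapter tail (the Read1 or Read2 sequencing-primer site), an optional
#' inline tag (heterogeneity spacer + index), and the locus-specific
#' primer.  No linker bases are inserted; IUPAC codes in the locus
#' primer are preserved.
#'
#' @param tail name of an adapter tail (see [adapter_tails()]) or a tail
#'   sequence itself.
#' @param tag a single-row subset of an [index_set()], or `NULL` for a
#'   non-indexed fusion.
#' @param locus a [locus_primer()].
#' @param flipped logical; marks primers from a "flipped" panel (tail
#'   swapped relative to the locus primer's usual read) in the name.
#' @param chemistry chemistry label used in the name; inferred from
#'   `tail` when it is a tail name.
#' @return An object of class `fusion_primer` with fields `name`,
#'   `tail_name`, `tail`, `tag_label`, `spacer`, `index`, `locus`,
#'   `sequence` (uppercase) and `annotated` (lowercase spacer retained).
#' @examples
#' s <- default_index_set()
#' fp <- build_fusion_primer("TruSeq_Read1", s[s$label == "A", ],
#'                           locus_primer("Pleth_12S_F",
#'                                        "AAAAAAGTCAGGTCAAGG", "forward"))
#' fp$sequence
#' @export
build_fusion_primer <- function(tail, tag = NULL, locus,
                                flipped = FALSE, chemistry = NULL) {
  if (tail %in% names(.ADAPTER_TAILS)) {
    tail_name <- tail
    tail_seq <- unname(.ADAPTER_TAILS[tail])
    if (is.null(chemistry))
      chemistry <- tolower(sub("_Read[12]$", "", tail_name))
  } else {
    tail_name <- "custom"
    tail_seq <- toupper(tail)
    if (is.null(chemistry)) chemistry <- "custom"
  }
  if (!inherits(locus, "locus_primer"))
    stop("'locus' must be a locus_primer")
  spacer <- ""; idx <- ""; tag_label <- "NoTag"
  if (!is.null(tag) && nrow(as.data.frame(tag))) {
    tag <- as.data.frame(tag)
    if (nrow(tag) != 1L) stop("'tag' must be a single tag")
    spacer <- tag$spacer; idx <- tag$index; tag_label <- tag$label
  }
  read <- if (grepl("Read2$", tail_name)) "R2" else "R1"
  name <- paste0(locus$name, "_", chemistry, "_", read, "_", tag_label,
                 if (flipped) "_flip" else "")
  annotated <- paste0(tail_seq, tolower(spacer), toupper(idx),
                      locus$sequence)
  structure(list(name = name, tail_name = tail_name, tail = tail_seq,
                 tag_label = tag_label, spacer = tolower(spacer),
                 index = toupper(idx), locus = locus,
                 flipped = flipped, chemistry = chemistry,
                 sequence = toupper(annotated), annotated = annotated),
            class = "fusion_primer")
}

#' Build the full indexed fusion-primer panel for one locus
#'
#' The standard panel for one forward + reverse locus-primer pair
#' contains 22 primers: 2 non-indexed fusions (tail + locus primer) and
#' 20 internally indexed fusions (8 forward tags A-H on the Read1 side,
#' 12 reverse tags 1-12 on the Read2 side).  With `flipped = TRUE` a
#' second set of 22 is added in which the forward locus primer carries
#' the Read2 tail and vice versa (mitigating Read 2 quality bias);
#' tags stay with their locus primer, not with the tail.
#'
#' The index set is validated first and the panel is refused if its
#' design guarantees do not hold.
#'
#' @param forward,reverse [locus_primer()] objects.
#' @param chemistry `"truseq"` or `"nextera"`.
#' @param index_set an [index_set()] (default: [default_index_set()]).
#' @param flipped logical; also generate the tail-swapped panel.
#' @return An object of class `primer_panel`: a data frame with one row
#'   per primer (columns `name`, `chemistry`, `read`, `tag_label`,
#'   `locus_name`, `locus_orientation`, `flipped`, `sequence`,
#'   `annotated`, `length`).
#' @examples
#' fwd <- locus_primer("Pleth_12S_F", "AAAAAAGTCAGGTCAAGG", "forward")
#' rev <- locus_primer("Pleth_12S_R", "GGTGACGGGCGGTGTGTG", "reverse")
#' nrow(build_primer_panel(fwd, rev, "truseq"))   # 22
#' @export
build_primer_panel <- function(forward, reverse,
                               chemistry = c("truseq", "nextera"),
                               index_set = default_index_set(),
                               flipped = FALSE) {
  chemistry <- match.arg(chemistry)
  stopifnot(inherits(forward, "locus_primer"),
            inherits(reverse, "locus_primer"))
  if (identical(forward$sequence, reverse$sequence))
    stop("forward and reverse locus primers must differ")
  val <- validate_index_set(index_set)
  if (!val$passed) {
    print(val)
    stop("index set failed validation; refusing to build a panel")
  }
  tails <- adapter_tails(chemistry)
  fwd_tags <- forward_tags(index_set)
  rev_tags <- reverse_tags(index_set)

  one_side <- function(locus, tags, tail_name, flip) {
    prims <- list(build_fusion_primer(tail_name, NULL, locus,
                                      flipped = flip))
    for (i in seq_len(nrow(tags)))
      prims[[i + 1L]] <- build_fusion_primer(
        tail_name, tags[i, , drop = FALSE], locus, flipped = flip)
    prims
  }
  r1 <- names(tails)[1L]; r2 <- names(tails)[2L]
  prims <- c(one_side(forward, fwd_tags, r1, FALSE),
             one_side(reverse, rev_tags, r2, FALSE))
  if (flipped)
    prims <- c(prims,
               one_side(forward, fwd_tags, r2, TRUE),
               one_side(reverse, rev_tags, r1, TRUE))

  df <- do.call(rbind, lapply(prims, function(p)
    data.frame(name = p$name, chemistry = p$chemistry,
               read = if (grepl("Read2$", p$tail_name)) "R2" else "R1",
               tag_label = p$tag_label,
               locus_name = p$locus$name,
               locus_orientation = p$locus$orientation,
               flipped = p$flipped,
               sequence = p$sequence, annotated = p$annotated,
               length = nchar(p$sequence),
               stringsAsFactors = FALSE)))
  structure(df, index_set = index_set,
            class = c("primer_panel", "data.frame"))
}

#' @export
print.primer_panel <- function(x, ...) {
  cat(sprintf("Fusion-primer panel: %d primers (%s%s)\n", nrow(x),
              x$chemistry[1L],
              if (any(x$flipped)) ", incl. flipped" else ""))
  print(as.data.frame(x)[, c("name", "tag_label", "read", "length")],
        ...)
  cat("Note: secondary structures and other PCR-inhibiting",
      "characteristics are not checked; validate primers before",
      "ordering.\n")
  invisible(x)
}

#' 96-well combinatorial plate layout
#'
#' Maps each well of a 96-well plate to its forward/reverse tag
#' combination: plate row r (A-H) uses indexed forward primer r, plate
#' column c (1-12) uses indexed reverse primer c, so the 96 wells
#' exhaust the 8 x 12 tag combinations bijectively.
#'
#' @param panel a `primer_panel` with 8 indexed forward-locus and 12
#'   indexed reverse-locus primers (unflipped rows are used).
#' @return An object of class `plate_map`: data frame with columns
#'   `well`, `row`, `column`, `fwd_tag`, `rev_tag`, `fwd_primer`,
#'   `rev_primer`.
#' @examples
#' fwd <- locus_primer("F", "ACGTACGTACGT", "forward")
#' rev <- locus_primer("R", "TGCATGCATGCA", "reverse")
#' pm <- plate_layout(build_primer_panel(fwd, rev, "truseq"))
#' pm[pm$well == "A1", ]
#' @export
plate_layout <- function(panel) {
  p <- panel[!panel$flipped & panel$tag_label != "NoTag", , drop = FALSE]
  fwd <- p[p$locus_orientation == "forward", , drop = FALSE]
  rev <- p[p$locus_orientation == "reverse", , drop = FALSE]
  if (nrow(fwd) != 8L || nrow(rev) != 12L)
    stop("plate layout needs 8 indexed forward and 12 indexed reverse ",
         "primers; got ", nrow(fwd), " + ", nrow(rev))
  rows <- fwd$tag_label; cols <- rev$tag_label
  grid <- expand.grid(row = rows, column = cols,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(match(grid$row, rows), match(grid$column, cols)), ]
  out <- data.frame(
    well = paste0(grid$row, grid$column),
    row = grid$row, column = grid$column,
    fwd_tag = grid$row, rev_tag = grid$column,
    fwd_primer = fwd$name[match(grid$row, fwd$tag_label)],
    rev_primer = rev$name[match(grid$column, rev$tag_label)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("plate_map", "data.frame"))
}

#' Write / read a primer order sheet
#'
#' Writes the panel as a synthesis-ready CSV: columns `name`,
#' `sequence` (all uppercase; vendors ignore case), `length`, `read`,
#' `tag_label`, `locus_name`, `chemistry`, `flipped`, and `annotated`
#' (lowercase spacer retained for readability).
#'
#' @param panel a `primer_panel`.
#' @param path output file path.
#' @return `write_order_sheet()` returns `path` invisibly;
#'   `read_order_sheet()` returns the sheet as a data frame.
#' @export
write_order_sheet <- function(panel, path) {
  if (!nrow(panel)) stop("empty panel")
  df <- as.data.frame(panel)[, c("name", "sequence", "length", "read",
                                 "tag_label", "locus_name", "chemistry",
                                 "flipped", "annotated")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_order_sheet
#' @export
read_order_sheet <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(tag_label = "character"))
}
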