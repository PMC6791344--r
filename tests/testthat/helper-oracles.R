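# Independent oracles and small fixture builders used across tests.

# Plain dynamic-programming Levenshtein distance (unit costs), kept
# independent of the distance used inside the package.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1L] <- 0:length(x)
  d[1L, ] <- 0:length(y)
  for (i in seq_along(x))
    for (j in seq_along(y))
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + (x[i] != y[j]))
  d[length(x) + 1L, length(y) + 1L]
}

# character-by-character Hamming distance on the shared prefix
ham_chars <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, n), "")[[1]] !=
      strsplit(substr(b, 1, n), "")[[1]])
}

test_fwd_primer <- function() {
  locus_primer("Pleth_12S_F", "AAAAAAGTCAGGTCAAGG", "forward")
}

test_rev_primer <- function() {
  locus_primer("Pleth_12S_R", "GGTGACGGGCGGTGTGTG", "reverse")
}

# all single-base substitution variants of a sequence
substitution_variants <- function(seq) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (p in seq_along(ch))
    for (b in setdiff(bases, ch[p])) {
      v <- ch
      v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  out
}
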