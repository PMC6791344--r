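## Minimal FASTQ IO on top of Biostrings.  Reads are held in memory as
## plain character vectors (amplicon pools at the scales handled here
## are small); gzip input is detected transparently by the connection
## layer from the file's magic bytes, never from its extension.

.read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L)
    return(list(id = character(0), seq = character(0),
                qual = character(0)))
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(id = names(x), seq = as.character(x),
       qual = as.character(Biostrings::quality(x)))
}

.write_fastq <- function(id, seq, qual, path, compress = FALSE) {
  dna <- Biostrings::DNAStringSet(seq)
  names(dna) <- id
  ## Biostrings warns when dropping (empty) metadata columns on write
  withCallingHandlers(
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = compress),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

## read-pair identity: first header token without a trailing /1 or /2
.read_key <- function(id) sub("/[12]$", "", sub("[ \t].*$", "", id))
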