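#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' Format is auto-detected from the first record character (`>` FASTA,
#' `@` FASTQ) and gzip from the magic bytes.  Sequences are uppercased;
#' FASTQ qualities are dropped.  Identifiers are truncated at the first
#' whitespace.
#'
#' @param path Input file.
#' @return Named character vector of sequences, file order.
#' @export
read_seqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- gzfile(path, "rt") # transparently reads plain files too
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) return(stats::setNames(character(0), NULL))
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop("cannot detect FASTA/FASTQ format in ", path,
                   " (first record starts with '",
                   substr(first, 1, 1), "')", call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences as FASTA
#'
#' Multi-line FASTA wrapped at 80 columns.
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
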