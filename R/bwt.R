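new_rle_bwt <- function(run_symbols, run_lengths, total_counts, num_strings,
                        length) {
  stopifnot(length(run_symbols) == length(run_lengths))
  names(total_counts) <- LR_ALPHABET
  obj <- structure(
    list(run_symbols = as.integer(run_symbols),
         run_lengths = as.numeric(run_lengths),
         total_counts = total_counts,
         num_strings = as.numeric(num_strings),
         length = as.numeric(length)),
    class = "RleBwt")
  validate_rle_bwt(obj)
}

validate_rle_bwt <- function(x) {
  if (length(x$run_lengths) > 0 && any(x$run_lengths < 1))
    stop("RleBwt has a non-positive run length", call. = FALSE)
  if (!isTRUE(all.equal(sum(x$run_lengths), x$length)))
    stop("RleBwt run lengths do not sum to the stated length", call. = FALSE)
  if (!isTRUE(all.equal(sum(x$total_counts), x$length)))
    stop("RleBwt symbol totals do not sum to the stated length", call. = FALSE)
  if (x$total_counts[["$"]] != x$num_strings)
    stop("RleBwt terminator count does not match the number of strings",
         call. = FALSE)
  x
}

#' Build the multi-string BWT of a short-read set
#'
#' Computes the Burrows-Wheeler transform of a collection of reads, one
#' terminator (`$`) per read.  Terminators sort before all bases and, among
#' themselves, by read index, which makes the transform deterministic for a
#' fixed input ordering.  Sequences are uppercased on ingest; soft-masked
#' bases lose their masking.
#'
#' @param reads Character vector (or `Biostrings::XStringSet`) of reads over
#'   A/C/G/N/T after uppercasing.  Must all be non-empty.
#' @return An object of class `RleBwt`: the run-length-encoded BWT over the
#'   ordered alphabet `$`, A, C, G, N, T, with per-symbol totals and the
#'   number of indexed strings.
#' @examples
#' bwt <- build_msbwt(c("ACGT"))
#' bwt_string(bwt)  # "T$ACG"
#' @seealso [build_fm_index()], [save_rle()]
#' @export
build_msbwt <- function(reads) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(as.character(reads))
  if (length(reads) == 0) {
    return(new_rle_bwt(integer(0), numeric(0), numeric(6), 0, 0))
  }
  res <- cpp_build_msbwt(reads)
  new_rle_bwt(res$run_symbols, res$run_lengths, res$total_counts,
              res$num_strings, res$length)
}

#' Decode a run-length-encoded BWT to a plain string
#'
#' Mostly useful for inspection and testing on small inputs.
#'
#' @param bwt An `RleBwt`.
#' @return The BWT as a single string over `$ACGNT`.
#' @export
bwt_string <- function(bwt) {
  stopifnot(inherits(bwt, "RleBwt"))
  if (length(bwt$run_symbols) == 0) return("")
  paste(rep(LR_ALPHABET[bwt$run_symbols + 1L], bwt$run_lengths),
        collapse = "")
}

#' @export
print.RleBwt <- function(x, ...) {
  cat(sprintf("RleBwt: %s symbols in %s runs, %s strings\n",
              format(x$length, big.mark = ","),
              format(length(x$run_symbols), big.mark = ","),
              format(x$num_strings, big.mark = ",")))
  cat("  totals:", paste(sprintf("%s=%g", names(x$total_counts),
                                 x$total_counts), collapse = " "), "\n")
  invisible(x)
}

#' Serialize / load a run-length-encoded BWT
#'
#' The on-disk dialect is a flat byte array with no header: each byte holds a
#' symbol index (0-5 for `$ACGNT`) in its low 3 bits and a 5-bit run-length
#' chunk in its high 5 bits.  Consecutive bytes carrying the same symbol
#' extend the run as `length += chunk << (5*j)` for the j-th continuation
#' byte.  `save_rle()` followed by `load_rle()` is a bit-exact identity.
#'
#' @param bwt An `RleBwt`.
#' @param path File path to write to / read from.
#' @return `save_rle()` returns `path` invisibly; `load_rle()` returns an
#'   `RleBwt`.  Malformed input (symbol index 6 or 7, zero-length run) is
#'   rejected with the offending byte offset.
#' @export
save_rle <- function(bwt, path) {
  stopifnot(inherits(bwt, "RleBwt"))
  bytes <- cpp_rle_to_bytes(bwt$run_symbols, bwt$run_lengths)
  writeBin(bytes, path)
  invisible(path)
}

#' @rdname save_rle
#' @export
load_rle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = file.size(path))
  res <- cpp_bytes_to_rle(bytes)
  new_rle_bwt(res$run_symbols, res$run_lengths, res$total_counts,
              res$num_strings, res$length)
}
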