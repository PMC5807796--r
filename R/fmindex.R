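#' Build an FM-index over a run-length-encoded BWT
#'
#' The FM-index answers rank/occurrence queries over the BWT and, through
#' backward search, exact k-mer frequency lookups for *any* k — it is an
#' implicit representation of every de Bruijn graph of the indexed reads at
#' once.  Two interchangeable occupancy structures are provided: per-symbol
#' bit arrays with constant-time rank (the default; faster, larger) and
#' sampled occurrence checkpoints with a configurable sampling rate
#' (slower, smaller).  Both answer every query identically.
#'
#' @param bwt An [`RleBwt`][build_msbwt] object.
#' @param implementation `"bitarray"` (default) or `"sampled"`.
#' @param sample_rate Checkpoint spacing for the sampled implementation;
#'   ignored by the bit-array implementation.  Must be >= 1.
#' @return An object of class `FmIndex` holding the rank structure, the
#'   cumulative symbol offsets (C array) and index metadata.  The structure
#'   lives in memory only; rebuild it from the `RleBwt` rather than
#'   serialising it.
#' @examples
#' fm <- build_fm_index(build_msbwt(c("ACGT", "TTTT")))
#' count_kmer(fm, "TTT")
#' @export
build_fm_index <- function(bwt, implementation = c("bitarray", "sampled"),
                           sample_rate = 64L) {
  stopifnot(inherits(bwt, "RleBwt"))
  implementation <- match.arg(implementation)
  sample_rate <- as.integer(sample_rate)
  if (is.na(sample_rate) || sample_rate < 1L)
    stop("sample_rate must be a positive integer", call. = FALSE)
  ptr <- cpp_fm_build(bwt$run_symbols, bwt$run_lengths, implementation,
                      sample_rate)
  structure(
    list(ptr = ptr,
         implementation = implementation,
         sample_rate = sample_rate,
         length = bwt$length,
         num_strings = bwt$num_strings,
         total_counts = bwt$total_counts,
         alphabet_offsets = stats::setNames(cpp_fm_offsets(ptr),
                                            c(LR_ALPHABET, "total"))),
    class = "FmIndex")
}

#' @export
print.FmIndex <- function(x, ...) {
  cat(sprintf("FmIndex (%s): %s symbols, %s strings\n", x$implementation,
              format(x$length, big.mark = ","),
              format(x$num_strings, big.mark = ",")))
  invisible(x)
}

#' Rank query over the indexed BWT
#'
#' `fm_rank(fm, symbol, p)` is the number of occurrences of `symbol` in the
#' BWT prefix `[0, p)`.  Nondecreasing in `p`; at `p = length` it equals the
#' symbol's total count.
#'
#' @param fm An `FmIndex`.
#' @param symbol One of `"$" "A" "C" "G" "N" "T"`.
#' @param p Position in `[0, length]`.
#' @return Occurrence count (numeric scalar).
#' @export
fm_rank <- function(fm, symbol, p) {
  stopifnot(inherits(fm, "FmIndex"))
  idx <- match(symbol, LR_ALPHABET) - 1L
  if (is.na(idx)) stop("unknown symbol: ", symbol, call. = FALSE)
  vapply(p, function(pp) cpp_fm_rank(fm$ptr, idx, pp), numeric(1))
}

#' Exact k-mer frequency from the FM-index
#'
#' Counts occurrences of each k-mer as a substring of any indexed read
#' *plus* occurrences of its reverse complement, each by backward search
#' (O(k) rank steps per strand).  Both strands are always queried and
#' summed, even for reverse-complement palindromes (which therefore count
#' double); downstream thresholds absorb the doubling uniformly.
#'
#' @param fm An `FmIndex`.
#' @param kmer Character vector of k-mers over A/C/G/N/T (k >= 1).  The
#'   complement of N is N.
#' @return Numeric vector of frequencies; a k-mer longer than every indexed
#'   read simply has frequency 0.
#' @examples
#' fm <- build_fm_index(build_msbwt("AAAA"))
#' count_kmer(fm, "AAA")  # 2 forward, 0 reverse complement
#' @export
count_kmer <- function(fm, kmer) {
  stopifnot(inherits(fm, "FmIndex"))
  kmer <- as.character(kmer)
  if (length(kmer) == 0) return(numeric(0))
  .validate_dna(kmer, "k-mer")
  cpp_count_kmers(fm$ptr, kmer)
}

#' Successor / predecessor frequencies of a k-mer
#'
#' Edges of the implicit de Bruijn graph: for `direction = "right"` the
#' frequencies of `kmer[2..k] + b`, for `"left"` those of
#' `b + kmer[1..k-1]`, for each base b in A, C, G, T (in that order).
#' Zero-frequency bases are omitted.  Only A/C/G/T are ever proposed;
#' N-containing k-mers are countable but never generated as extensions.
#'
#' @param fm An `FmIndex`.
#' @param kmer A single k-mer (length >= 1).
#' @param direction `"right"` or `"left"`.
#' @return A data frame with columns `base` and `frequency`, rows in
#'   A<C<G<T order.
#' @export
extend_kmer <- function(fm, kmer, direction = c("right", "left")) {
  stopifnot(inherits(fm, "FmIndex"), length(kmer) == 1)
  direction <- match.arg(direction)
  .validate_dna(kmer, "k-mer")
  freqs <- cpp_extend_kmer(fm$ptr, kmer, direction == "right")
  keep <- freqs > 0
  data.frame(base = c("A", "C", "G", "T")[keep],
             frequency = freqs[keep],
             stringsAsFactors = FALSE)
}

# Per-position both-strand k-mer counts along a read; numeric(0) when the
# read is shorter than k.
kmer_counts <- function(fm, read, k) {
  stopifnot(inherits(fm, "FmIndex"))
  .validate_dna(read, "read")
  cpp_read_kmer_counts(fm$ptr, read, as.integer(k))
}
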