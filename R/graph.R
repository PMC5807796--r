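#' Solidity of a k-mer at a frequency threshold
#'
#' A k-mer is *solid* when its both-strand frequency is at least `t`, and
#' *weak* when the frequency is strictly below `t`.
#'
#' @param fm An `FmIndex`.
#' @param kmer Character vector of k-mers.
#' @param t Threshold, >= 1.
#' @return Logical vector: `TRUE` for solid.
#' @export
is_solid <- function(fm, kmer, t) {
  stopifnot(t >= 1)
  count_kmer(fm, kmer) >= t
}

.check_limits <- function(branch_limit, min_length, max_length) {
  if (branch_limit < 1) stop("branch_limit must be >= 1", call. = FALSE)
  if (min_length > max_length)
    stop("min_length must not exceed max_length", call. = FALSE)
}

.paths_df <- function(res) {
  out <- data.frame(sequence = unlist(res$sequences, use.names = FALSE),
                    min_interior_frequency = unlist(res$min_freqs,
                                                    use.names = FALSE),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- data.frame(sequence = character(0),
                      min_interior_frequency = numeric(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "exhausted") <- isTRUE(res$exhausted)
  attr(out, "reversed") <- isTRUE(res$reversed)
  out
}

#' Seed-and-bridge traversal between two solid anchor k-mers
#'
#' Depth-first traversal of the implicit de Bruijn graph pruned at
#' threshold `t`, from `seed` toward `target`: returns every path (up to
#' the branch budget and path cap) that starts with the seed k-mer, ends
#' with the target k-mer, and whose total length in bases lies in
#' `[min_length, max_length]`.  Edges are explored in A<C<G<T order, so the
#' result order is deterministic.  If the forward traversal yields no
#' path, the traversal is retried from the reverse complement of the
#' target toward the reverse complement of the seed and any results are
#' flipped back — branching concentrated near the seed can make the
#' reverse direction succeed where the forward one exhausts its budget.
#'
#' The branch budget charges one unit at every expanded node with two or
#' more qualifying successors; exceeding it aborts the traversal,
#' returning the complete paths found so far (possibly none) — never an
#' error.
#'
#' @param fm An `FmIndex`.
#' @param seed,target Anchor k-mers of equal length, both expected to be
#'   solid at `t`.
#' @param t Frequency threshold in force.
#' @param branch_limit Branch budget L (see above).
#' @param min_length,max_length Inclusive bounds on path length in bases.
#' @param max_paths Cap on retained paths (first found); default 10.
#' @return Data frame with columns `sequence` and
#'   `min_interior_frequency` (the smallest k-mer frequency along the
#'   path), plus attributes `exhausted` and `reversed`.
#' @export
bridge_paths <- function(fm, seed, target, t, branch_limit,
                         min_length, max_length, max_paths = 10L) {
  stopifnot(inherits(fm, "FmIndex"), length(seed) == 1, length(target) == 1)
  .validate_dna(c(seed, target), "anchor k-mer")
  .check_limits(branch_limit, min_length, max_length)
  res <- cpp_bridge(fm$ptr, seed, target, t, branch_limit,
                    min_length, max_length, as.integer(max_paths))
  .paths_df(res)
}

#' Seed-and-extend traversal from a single solid anchor
#'
#' Depth-first extension used for weak regions at a read end.  Returns the
#' maximal paths whose length falls within `[min_length, max_length]`:
#' a path is recorded when it reaches `max_length` or dies (no qualifying
#' successor) at a length of at least `min_length`; paths that die earlier
#' are discarded.  `direction = "head"` extends leftward, implemented as a
#' rightward traversal on the reverse complement strand, so returned
#' sequences *end* with the seed k-mer; `"tail"` paths *start* with it.
#'
#' @inheritParams bridge_paths
#' @param seed The anchor k-mer, expected solid at `t`.
#' @param direction `"tail"` (rightward) or `"head"` (leftward).
#' @return As [bridge_paths()].
#' @export
extend_paths <- function(fm, seed, t, branch_limit, min_length, max_length,
                         direction = c("tail", "head"), max_paths = 10L) {
  stopifnot(inherits(fm, "FmIndex"), length(seed) == 1)
  direction <- match.arg(direction)
  .validate_dna(seed, "anchor k-mer")
  .check_limits(branch_limit, min_length, max_length)
  res <- cpp_extend_paths(fm$ptr, seed, t, branch_limit, min_length,
                          max_length, as.integer(max_paths),
                          direction == "head")
  .paths_df(res)
}

# Path-length bounds for a weak-region replacement expected to span E
# bases: generous slack because indel-dominated long-read error makes
# exact-length bridges wrong.
.span_limits <- function(k, span) {
  list(min_length = max(k, floor(0.5 * span)),
       max_length = ceiling(1.5 * span) + k)
}
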