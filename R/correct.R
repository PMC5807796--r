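#' Correction parameters
#'
#' Bundles the five tunables of the two-pass corrector.  `k` is the
#' short-pass k-mer size and `K` the long-pass size (`NULL`, `NA` or `0`
#' disables the second pass); `T` is the absolute minimum solid frequency;
#' `F` the fraction of the per-read median solid frequency; `B` the branch
#' limit factor, giving a per-pass branch budget `L = B * k`.
#'
#' @param k Short k-mer size (default 21).
#' @param K Long K-mer size (default 59); must exceed `k` when present.
#' @param T Absolute minimum solid frequency (default 5).
#' @param F Fraction of the median solid frequency (default 0.10).
#' @param B Branch limit factor (default 4).
#' @param strict_median If `TRUE`, only frequencies strictly greater than
#'   `T` enter the median list (default `FALSE`: at-or-above `T`).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(k = 21L, K = 59L, T = 5L, F = 0.10, B = 4L,
                              strict_median = FALSE) {
  k <- as.integer(k)
  if (!is.null(K) && (is.na(K) || K == 0)) K <- NULL
  if (!is.null(K)) {
    K <- as.integer(K)
    if (k >= K) stop("k must be smaller than K", call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (F < 0 || F > 1) stop("F must lie in [0, 1]", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  structure(list(k = k, K = K, T = as.numeric(T), F = as.numeric(F),
                 B = as.numeric(B), strict_median = isTRUE(strict_median)),
            class = "correction_params")
}

#' @export
print.correction_params <- function(x, ...) {
  cat(sprintf("correction_params: k=%d K=%s T=%g F=%g B=%g\n", x$k,
              if (is.null(x$K)) "-" else x$K, x$T, x$F, x$B))
  invisible(x)
}

#' Per-read dynamic solidity threshold
#'
#' From the k-mer frequencies observed along one long read, frequencies at
#' or above the absolute minimum `T` form a list whose median is the
#' read's *median solid frequency* m (m = 0 when the list is empty, as is
#' typical for low-coverage data).  The threshold in force for the read is
#' `t = max(T, ceiling(F * m))`: the ceiling keeps integer-valued counts
#' conservative.
#'
#' @param frequencies Numeric vector of per-k-mer counts along the read.
#' @param T Absolute minimum solid frequency (>= 1).
#' @param F Fraction of the median in `[0, 1]`.
#' @param strict If `TRUE`, the median list takes frequencies strictly
#'   greater than `T`.
#' @return The threshold t (numeric scalar, integer-valued).
#' @examples
#' dynamic_threshold(c(10, 20, 100), T = 5, F = 0.5)  # m = 20, t = 10
#' @export
dynamic_threshold <- function(frequencies, T = 5, F = 0.10, strict = FALSE) {
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  if (F < 0 || F > 1) stop("F must lie in [0, 1]", call. = FALSE)
  solid <- if (strict) frequencies[frequencies > T]
           else frequencies[frequencies >= T]
  m <- if (length(solid) == 0) 0 else stats::median(solid)
  max(T, ceiling(F * m))
}

#' Decompose a read into weak and solid regions
#'
#' Classifies every k-mer of the read as weak (frequency strictly below
#' `t`) or solid, and merges maximal runs of equal classification into
#' regions over 0-based, half-open k-mer start indices.
#'
#' @param read A single read sequence.
#' @param k K-mer size.
#' @param fm An `FmIndex`.
#' @param t Threshold in force.
#' @return Data frame with columns `kind` (`"weak"`/`"solid"`), `start`,
#'   `end`.  Empty (zero rows) when the read is shorter than `k`.
#' @export
classify_and_segment <- function(read, k, fm, t) {
  counts <- kmer_counts(fm, read, k)
  segment_counts(counts, t)
}

# Region decomposition from a precomputed count vector.
segment_counts <- function(counts, t) {
  if (length(counts) == 0) {
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  solid <- counts >= t
  r <- rle(solid)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  data.frame(kind = ifelse(r$values, "solid", "weak"),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# Deterministic candidate selection: smallest edit distance to the
# original segment, ties to the larger minimum interior frequency, then
# lexicographically smallest sequence.  Bridge candidates are compared
# whole (both ends anchored); extension candidates stop at a length
# bound rather than an anchor, so each is first trimmed to the prefix
# (tail) or suffix (head) that best fits the original segment.
select_candidate <- function(candidates, original, mode = "bridge",
                             min_keep = 0L) {
  if (nrow(candidates) == 0) return(NULL)
  seqs <- candidates$sequence
  minfreq <- candidates$min_interior_frequency
  if (mode %in% c("tail", "head")) {
    rev1 <- function(s) paste(rev(strsplit(s, NULL)[[1]]), collapse = "")
    orig_cmp <- if (mode == "head") rev1(original) else original
    fits <- lapply(seqs, function(s) {
      cpp_best_prefix(orig_cmp, if (mode == "head") rev1(s) else s)
    })
    # a path that was used up in full yet is shorter than the original
    # segment died inside the weak region: accepting it would clip the
    # read end, so it is no candidate at all
    spans <- vapply(seq_along(seqs), function(i) {
      fits[[i]]$prefix_len < nchar(seqs[i]) ||
        nchar(seqs[i]) >= nchar(original)
    }, logical(1))
    if (!any(spans)) return(NULL)
    seqs <- seqs[spans]
    fits <- fits[spans]
    minfreq <- minfreq[spans]
    seqs <- vapply(seq_along(seqs), function(i) {
      keep <- max(fits[[i]]$prefix_len, min_keep)
      if (mode == "head")
        substr(seqs[i], nchar(seqs[i]) - keep + 1L, nchar(seqs[i]))
      else substr(seqs[i], 1L, keep)
    }, character(1))
    d <- vapply(fits, function(f) f$distance, integer(1))
  } else {
    d <- vapply(seqs, cpp_levenshtein, integer(1), b = original,
                USE.NAMES = FALSE)
  }
  ord <- order(d, -minfreq, seqs)
  list(sequence = seqs[ord[1]], distance = d[ord[1]])
}

#' Repair one weak region of a read
#'
#' Selects anchors and traversal mode from the flanks of the weak region:
#' two flanking solid regions trigger a seed-and-bridge between the two
#' closest solid k-mers; a single flank triggers a seed-and-extend into
#' the read head or tail; no flank (the whole read weak) leaves the read
#' unchanged, as there is no start point for a traversal.  Candidate paths
#' are compared with the original read segment spanning the same anchors
#' (anchors included) and the candidate with the smallest edit distance
#' replaces it; when no candidate is found, no change is made.
#'
#' @param read The read sequence.
#' @param fm An `FmIndex`.
#' @param k K-mer size in force.
#' @param t Threshold in force.
#' @param branch_limit Branch budget L.
#' @param weak_start,weak_end The weak region, as 0-based half-open k-mer
#'   indices (as returned by [classify_and_segment()]).
#' @return `NULL` for no change, else a list with `start`/`end` (0-based,
#'   half-open base coordinates of the replaced segment) and `replacement`.
#' @export
repair_region <- function(read, fm, k, t, branch_limit, weak_start,
                          weak_end) {
  n_kmers <- nchar(read) - k + 1L
  has_left <- weak_start > 0L
  has_right <- weak_end < n_kmers
  if (!has_left && !has_right) return(NULL)

  if (has_left && has_right) {
    seed_start <- weak_start - 1L          # closest solid k-mer on the left
    seg_start <- seed_start                # bases, 0-based
    seg_end <- weak_end + k                # includes the right anchor
    seed <- substr(read, seed_start + 1L, seed_start + k)
    target <- substr(read, weak_end + 1L, weak_end + k)
    span <- seg_end - seg_start
    lim <- .span_limits(k, span)
    cand <- bridge_paths(fm, seed, target, t, branch_limit,
                         lim$min_length, lim$max_length)
  } else if (has_left) {                   # tail weak region
    seed_start <- weak_start - 1L
    seg_start <- seed_start
    seg_end <- nchar(read)
    seed <- substr(read, seed_start + 1L, seed_start + k)
    span <- seg_end - seg_start
    lim <- .span_limits(k, span)
    cand <- extend_paths(fm, seed, t, branch_limit,
                         lim$min_length, lim$max_length, direction = "tail")
  } else {                                 # head weak region
    seg_start <- 0L
    seg_end <- weak_end + k
    seed <- substr(read, weak_end + 1L, weak_end + k)
    span <- seg_end - seg_start
    lim <- .span_limits(k, span)
    cand <- extend_paths(fm, seed, t, branch_limit,
                         lim$min_length, lim$max_length, direction = "head")
  }

  mode <- if (has_left && has_right) "bridge"
          else if (has_left) "tail" else "head"
  original <- substr(read, seg_start + 1L, seg_end)
  best <- select_candidate(cand, original, mode = mode, min_keep = k)
  if (is.null(best) || best$sequence == original) return(NULL)
  list(start = seg_start, end = seg_end, replacement = best$sequence)
}

#' One correction pass at a single k-mer size
#'
#' Computes the read's k-mer frequencies, derives the dynamic threshold
#' `t` and branch budget `L = B * k`, segments the read into weak and
#' solid regions, and repairs the weak regions left to right, re-anchoring
#' coordinates after each replacement.  Reads shorter than `k`, or with no
#' weak region, pass through byte-identical.
#'
#' @param read A single read sequence.
#' @param k K-mer size for this pass.
#' @param params A [correction_params()] object (supplies `T`, `F`, `B`).
#' @param fm An `FmIndex`.
#' @return The corrected read (character scalar).
#' @export
correct_pass <- function(read, k, params, fm) {
  if (nchar(read) < k) return(read)
  counts <- kmer_counts(fm, read, k)
  t <- dynamic_threshold(counts, params$T, params$F, params$strict_median)
  L <- params$B * k
  regions <- segment_counts(counts, t)
  weak <- regions[regions$kind == "weak", , drop = FALSE]
  if (nrow(weak) == 0) return(read)

  pieces <- character(0)
  pos <- 0L # bases of `read` emitted so far (0-based prefix length)
  for (i in seq_len(nrow(weak))) {
    rep <- repair_region(read, fm, k, t, L, weak$start[i], weak$end[i])
    if (is.null(rep)) next
    replacement <- rep$replacement
    if (rep$start < pos) {
      # adjacent repairs share a single-k-mer solid anchor; the already
      # emitted anchor prefix is identical to the candidate's head
      replacement <- substr(replacement, pos - rep$start + 1L,
                            nchar(replacement))
    } else if (rep$start > pos) {
      pieces <- c(pieces, substr(read, pos + 1L, rep$start))
    }
    pieces <- c(pieces, replacement)
    pos <- rep$end
  }
  if (pos < nchar(read)) pieces <- c(pieces, substr(read, pos + 1L,
                                                    nchar(read)))
  paste(pieces, collapse = "")
}

#' Correct one long read (two-pass driver)
#'
#' Runs [correct_pass()] with the short k-mer, then — when `params$K` is
#' present — a second, programmatically identical pass with the long
#' K-mer on the intermediate result.  The threshold `t` and branch budget
#' `L` are recomputed per pass.
#'
#' @param read A single read sequence.
#' @param params A [correction_params()] object.
#' @param fm An `FmIndex`.
#' @return The corrected read (character scalar).
#' @export
correct_read <- function(read, params, fm) {
  out <- correct_pass(read, params$k, params, fm)
  if (!is.null(params$K)) out <- correct_pass(out, params$K, params, fm)
  out
}

#' Correct a set of long reads
#'
#' Applies [correct_read()] to each read independently; output order (and
#' names) equal input order.  With `processes > 1` the reads are corrected
#' in parallel via forked workers; per-read independence makes the result
#' observationally identical to the sequential run.
#'
#' @param reads Named character vector of read sequences.
#' @param fm An `FmIndex`.
#' @param params A [correction_params()] object.
#' @param processes Number of worker processes (default 1).
#' @return Named character vector of corrected reads, input order.
#' @export
correct_reads <- function(reads, fm, params = correction_params(),
                          processes = 1L) {
  ids <- names(reads)
  reads <- toupper(as.character(reads))
  if (length(reads) == 0) return(character(0))
  if (processes > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(reads, correct_read, params = params, fm = fm,
                              mc.cores = processes, mc.preschedule = TRUE)
    out <- unlist(out, use.names = FALSE)
  } else {
    out <- vapply(reads, correct_read, character(1), params = params,
                  fm = fm, USE.NAMES = FALSE)
  }
  stats::setNames(out, ids)
}
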