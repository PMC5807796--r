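#' Per-locus correction statistics
#'
#' Bundles the per-reference-locus confusion counts of an error-correction
#' experiment and their derived ratios:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), and
#' gain = (TP - FP) / (TP + FN) — the net fraction of input errors removed
#' by correction (negative when correction introduces more errors than it
#' fixes; never larger than sensitivity).
#'
#' A reference locus is *correct* in a read when it aligns to exactly one
#' matching read nucleotide, and *erroneous* when mismatched or deleted.
#' TP: erroneous before, correct after.  FP: correct before, erroneous
#' after.  FN: erroneous before and after.  TN: correct before and after.
#'
#' @param TP,FP,FN,TN Non-negative per-locus counts.
#' @param identity_before,identity_after Optional fraction of correct loci
#'   before/after correction.
#' @return An object of class `correction_stats`.
#' @examples
#' s <- correction_stats(TP = 8, FP = 1, FN = 2, TN = 100)
#' s$gain  # 0.7
#' @export
correction_stats <- function(TP, FP, FN, TN, identity_before = NA_real_,
                             identity_after = NA_real_) {
  counts <- c(TP, FP, FN, TN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 aligned_bases = TP + FP + FN + TN,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 gain = (TP - FP) / (TP + FN),
                 identity_before = identity_before,
                 identity_after = identity_after),
            class = "correction_stats")
}

#' @export
print.correction_stats <- function(x, ...) {
  cat(sprintf("correction_stats over %g reference loci\n", x$aligned_bases))
  cat(sprintf("  TP=%g FP=%g FN=%g TN=%g\n", x$TP, x$FP, x$FN, x$TN))
  cat(sprintf("  sensitivity=%.4f specificity=%.4f gain=%.4f\n",
              x$sensitivity, x$specificity, x$gain))
  if (!is.na(x$identity_before))
    cat(sprintf("  per-base identity %.4f -> %.4f\n", x$identity_before,
                x$identity_after))
  invisible(x)
}

# Reference-locus status of one read against its true origin interval:
# logical, TRUE where the locus aligns to a single matching nucleotide.
.locus_status <- function(read, genome, start, end, strand) {
  ref <- substr(genome, start + 1L, end)
  if (strand == "-") ref <- revcomp(ref)
  cpp_align_ref_status(ref, read)
}

#' Score corrected reads against the simulation truth
#'
#' Aligns each original and corrected read to its known origin interval by
#' global unit-cost edit-distance alignment (no external aligner) and
#' classifies every reference locus before/after correction, aggregating
#' TP, FP, FN, TN across reads (see [correction_stats()] for the
#' definitions).  A zero-length corrected read counts every locus of its
#' origin interval as FN.
#'
#' @param original Named character vector of uncorrected reads.
#' @param corrected Character vector of corrected reads, same order.
#' @param truth Truth data frame from [simulate_reads()].
#' @param genome Genome sequence the truth refers to.
#' @return A [correction_stats()] object, with per-base identities before
#'   and after correction filled in.
#' @export
score_correction <- function(original, corrected, truth, genome) {
  if (length(original) != length(corrected))
    stop("original and corrected read sets differ in length", call. = FALSE)
  ids <- names(original)
  if (!is.null(ids)) {
    miss <- setdiff(ids, truth$read_id)
    if (length(miss) > 0)
      stop("reads missing from the truth map: ", miss[1], call. = FALSE)
    truth <- truth[match(ids, truth$read_id), , drop = FALSE]
  }
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(original)) {
    before <- .locus_status(original[[i]], genome, truth$start[i],
                            truth$end[i], truth$strand[i])
    if (nchar(corrected[[i]]) == 0) {
      fn <- fn + length(before)
      next
    }
    after <- .locus_status(corrected[[i]], genome, truth$start[i],
                           truth$end[i], truth$strand[i])
    tp <- tp + sum(!before & after)
    fp <- fp + sum(before & !after)
    fn <- fn + sum(!before & !after)
    tn <- tn + sum(before & after)
  }
  total <- tp + fp + fn + tn
  correction_stats(tp, fp, fn, tn,
                   identity_before = (tn + fp) / total,
                   identity_after = (tn + tp) / total)
}
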