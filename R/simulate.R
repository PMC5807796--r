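#' Simulation profile
#'
#' Describes a synthetic study: a random genome with planted repeats, a
#' low-error substitution-only short-read set, and a high-error,
#' indel-dominated long-read set with a per-read truth map.  The defaults
#' emulate a small bacterial-scale experiment: a 50 kb genome carrying two
#' copies of a 500 bp repeat, 100 bp short reads at 50x coverage with
#' 0.5\% substitution error, and 4 kb long reads at 20x coverage with
#' 15\% error split sub:ins:del = 1:5:4 (an indel-dominated profile
#' typical of raw single-molecule long reads).
#'
#' @param genome_length Genome size in bases.
#' @param repeat_length,repeat_copies Length and copy number of the
#'   planted repeat (0 copies disables it).
#' @param short_read_length,short_coverage,short_error_rate Short-read
#'   parameters; errors are substitutions only.
#' @param long_read_length,long_coverage,long_error_rate Long-read
#'   parameters; `long_error_rate` is the per-reference-base error
#'   probability.
#' @param error_mix Proportions of substitution, insertion and deletion
#'   among long-read errors; must sum to 1.
#' @param circular Treat the genome as circular when sampling short reads
#'   (default `TRUE`), so coverage is uniform with no tip ramp-down.
#'   Long reads are always sampled from the linear sequence.
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(genome_length = 50000L, repeat_length = 500L,
                        repeat_copies = 2L, short_read_length = 100L,
                        short_coverage = 50, short_error_rate = 0.005,
                        long_read_length = 4000L, long_coverage = 20,
                        long_error_rate = 0.15,
                        error_mix = c(sub = 0.1, ins = 0.5, del = 0.4),
                        circular = TRUE, seed = 1L) {
  rates <- c(short_error_rate, long_error_rate)
  if (any(rates < 0 | rates > 1))
    stop("error rates must lie in [0, 1]", call. = FALSE)
  if (!isTRUE(all.equal(sum(error_mix), 1)))
    stop("error_mix must sum to 1", call. = FALSE)
  if (length(error_mix) != 3) stop("error_mix needs sub, ins, del",
                                   call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 repeat_length = as.integer(repeat_length),
                 repeat_copies = as.integer(repeat_copies),
                 short_read_length = as.integer(short_read_length),
                 short_coverage = short_coverage,
                 short_error_rate = short_error_rate,
                 long_read_length = as.integer(long_read_length),
                 long_coverage = long_coverage,
                 long_error_rate = long_error_rate,
                 error_mix = stats::setNames(as.numeric(error_mix),
                                             c("sub", "ins", "del")),
                 circular = isTRUE(circular),
                 seed = as.integer(seed)),
            class = "sim_profile")
}

#' @export
print.sim_profile <- function(x, ...) {
  cat(sprintf(paste0("sim_profile: %d bp genome (%dx %d bp repeat), ",
                     "short %dbp@%gx err %g, long %dbp@%gx err %g, seed %d\n"),
              x$genome_length, x$repeat_copies, x$repeat_length,
              x$short_read_length, x$short_coverage, x$short_error_rate,
              x$long_read_length, x$long_coverage, x$long_error_rate,
              x$seed))
  invisible(x)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_subs <- function(seqs, rate) {
  # substitution-only errors, vectorised over the read set
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], NULL)[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# One long read from genome[start, start+L): per reference base the
# category is match, substitution, insertion-after, or deletion.  Returns
# the read sequence and its edit trace (ops over {=,X,I,D}, one I per
# inserted base).
.long_read_from <- function(ref_chars, e, mix) {
  L <- length(ref_chars)
  cat_probs <- c(1 - e, e * mix[["sub"]], e * mix[["ins"]], e * mix[["del"]])
  cats <- sample.int(4L, L, replace = TRUE, prob = cat_probs)
  bases <- c("A", "C", "G", "T")
  out <- ref_chars
  is_sub <- cats == 2L
  if (any(is_sub)) {
    # a uniformly chosen base different from the reference base
    shift <- sample.int(3L, sum(is_sub), replace = TRUE)
    out[is_sub] <- bases[(match(ref_chars[is_sub], bases) - 1L + shift) %% 4L
                         + 1L]
  }
  is_ins <- cats == 3L
  if (any(is_ins)) {
    out[is_ins] <- paste0(ref_chars[is_ins],
                          sample(bases, sum(is_ins), replace = TRUE))
  }
  out[cats == 4L] <- ""
  ops <- strsplit(paste(c("=", "X", "=I", "D")[cats], collapse = ""),
                  NULL)[[1]]
  list(seq = paste(out, collapse = ""), ops = ops)
}

.ops_to_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate a truth-known dataset
#'
#' Generates the genome, short reads and long reads described by a
#' [sim_profile()].  Reads are emitted on both strands.  Each long read
#' carries a truth record (origin interval, strand, per-base edit trace)
#' that makes alignment-free scoring possible.
#'
#' @param profile A [sim_profile()].
#' @return A list of class `sim_dataset` with elements `genome` (character
#'   scalar), `short_reads` and `long_reads` (named character vectors) and
#'   `truth` — a data frame with columns `read_id`, `start`, `end`
#'   (0-based, half-open genome interval), `strand` (`+`/`-`) and `cigar`
#'   (run-length `=XID` edit trace in reference order).
#' @export
simulate_reads <- function(profile) {
  stopifnot(inherits(profile, "sim_profile"))
  withr::with_seed(profile$seed, .simulate_impl(profile))
}

.simulate_impl <- function(p) {
  G <- p$genome_length
  genome <- .random_dna(G)
  if (p$repeat_copies > 0 && p$repeat_length > 0) {
    rep_seq <- .random_dna(p$repeat_length)
    # evenly spaced, non-overlapping copies
    slots <- floor(seq(from = G / (p$repeat_copies + 1),
                       by = G / (p$repeat_copies + 1),
                       length.out = p$repeat_copies))
    for (s in slots) {
      substr(genome, s + 1L, s + p$repeat_length) <- rep_seq
    }
  }

  # short reads: uniform starts, both strands, substitutions only
  srl <- p$short_read_length
  n_short <- ceiling(p$short_coverage * G / srl)
  if (n_short > 0) {
    if (p$circular) {
      starts <- sample.int(G, n_short, replace = TRUE)
      genome2 <- paste0(genome, substr(genome, 1L, srl))
      shorts <- substring(genome2, starts, starts + srl - 1L)
    } else {
      starts <- sample.int(G - srl + 1L, n_short, replace = TRUE)
      shorts <- substring(genome, starts, starts + srl - 1L)
    }
    shorts <- .mutate_subs(shorts, p$short_error_rate)
    flip <- runif(n_short) < 0.5
    shorts[flip] <- revcomp(shorts[flip])
    names(shorts) <- sprintf("short_%06d", seq_len(n_short))
  } else {
    shorts <- stats::setNames(character(0), NULL)
  }

  # long reads: linear sampling, indel-dominated errors, truth map
  lrl <- min(p$long_read_length, G)
  n_long <- ceiling(p$long_coverage * G / lrl)
  longs <- character(n_long)
  truth <- data.frame(read_id = sprintf("long_%05d", seq_len(n_long)),
                      start = integer(n_long), end = integer(n_long),
                      strand = character(n_long), cigar = character(n_long),
                      stringsAsFactors = FALSE)
  if (n_long > 0) {
    gchars <- strsplit(genome, NULL)[[1]]
    for (i in seq_len(n_long)) {
      s0 <- sample.int(G - lrl + 1L, 1L) - 1L # 0-based
      res <- .long_read_from(gchars[(s0 + 1L):(s0 + lrl)],
                             p$long_error_rate, p$error_mix)
      minus <- runif(1) < 0.5
      longs[i] <- if (minus) revcomp(res$seq) else res$seq
      truth$start[i] <- s0
      truth$end[i] <- s0 + lrl
      truth$strand[i] <- if (minus) "-" else "+"
      truth$cigar[i] <- .ops_to_cigar(res$ops)
    }
    names(longs) <- truth$read_id
  } else {
    longs <- stats::setNames(character(0), NULL)
    truth <- truth[0, , drop = FALSE]
  }

  structure(list(genome = genome, short_reads = shorts, long_reads = longs,
                 truth = truth, profile = p),
            class = "sim_dataset")
}

#' Write / read a truth map as TSV
#'
#' The sidecar format for the long-read truth map: tab-separated columns
#' `read_id`, `start`, `end`, `strand`, `cigar` with a header line.
#'
#' @param truth A truth data frame (see [simulate_reads()]).
#' @param path File path.
#' @return `write_truth_map()` returns `path` invisibly;
#'   `read_truth_map()` returns the data frame.
#' @export
write_truth_map <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_map
#' @export
read_truth_map <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "integer", "character",
                            "character"))
}
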