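# Independent oracles used across the suite.  Nothing here touches the
# package's BWT/FM-index machinery: counts come from direct scans of the
# read list, the reference BWT from sorting rotations, and graph paths
# from an explicitly materialised de Bruijn graph.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_reads <- function(n_reads, min_len = 4, max_len = 12) {
  vapply(seq_len(n_reads),
         function(i) rand_dna(sample(min_len:max_len, 1)), character(1))
}

# Rotation-sort BWT oracle.  '$' sorts below every base; ties among
# terminators break by string index.  Comparison beyond a terminator is
# irrelevant, so the sort key is the rotation truncated at its '$' (with
# symbols remapped to sort $ < A < C < G < N < T) plus the padded index.
naive_msbwt <- function(reads) {
  keys <- character(0)
  last <- character(0)
  for (s in seq_along(reads)) {
    rot_src <- paste0(reads[s], "$")
    L <- nchar(rot_src)
    doubled <- paste0(rot_src, rot_src)
    for (off in 0:(L - 1)) {
      rot <- substr(doubled, off + 1, off + L)
      dollar <- regexpr("$", rot, fixed = TRUE)
      key <- paste0(chartr("$ACGNT", "012345", substr(rot, 1, dollar)),
                    sprintf("%06d", s))
      keys <- c(keys, key)
      last <- c(last, substr(rot, L, L))
    }
  }
  paste(last[order(keys, method = "radix")], collapse = "")
}

# Overlapping substring count of a k-mer over the reads plus their
# reverse complements (Biostrings counts overlapping matches).
naive_count <- function(reads, kmer) {
  if (length(reads) == 0) return(0)
  set <- Biostrings::DNAStringSet(reads)
  fwd <- sum(Biostrings::vcountPattern(kmer, set, fixed = TRUE))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  fwd + sum(Biostrings::vcountPattern(rc, set, fixed = TRUE))
}

# Memoised k-mer counter for the explicit de Bruijn graph oracle.
make_counter <- function(reads) {
  memo <- new.env(parent = emptyenv())
  function(kmer) {
    if (is.null(memo[[kmer]])) memo[[kmer]] <- naive_count(reads, kmer)
    memo[[kmer]]
  }
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Exhaustive bridge enumeration on the explicit graph, mirroring the
# documented traversal semantics: DFS in A<C<G<T edge order, a path is
# recorded whenever it currently ends with the target and its length is
# within bounds (and the DFS keeps extending it), branches are charged
# one budget unit per node with >= 2 qualifying successors, and
# exceeding the budget aborts the whole traversal.
oracle_bridge_dir <- function(counter, seed, target, t, budget, min_len,
                              max_len, max_paths = 1000) {
  k <- nchar(seed)
  paths <- character(0)
  done <- FALSE
  rec <- function(seq) {
    if (done) return()
    len <- nchar(seq)
    if (len >= min_len && len <= max_len &&
        substr(seq, len - k + 1, len) == target) {
      paths[[length(paths) + 1]] <<- seq
      if (length(paths) >= max_paths) { done <<- TRUE; return() }
    }
    if (len >= max_len) return()
    ctx <- substr(seq, len - k + 2, len)
    succ <- paste0(ctx, c("A", "C", "G", "T"))
    cnt <- vapply(succ, counter, numeric(1))
    ok <- cnt >= t
    if (sum(ok) >= 2) {
      budget <<- budget - 1
      if (budget < 0) { done <<- TRUE; return() }
    }
    for (b in which(ok)) {
      if (done) return()
      rec(paste0(seq, c("A", "C", "G", "T")[b]))
    }
  }
  rec(seed)
  paths
}

oracle_bridge <- function(reads, seed, target, t, budget, min_len, max_len,
                          max_paths = 1000) {
  counter <- make_counter(reads)
  fwd <- oracle_bridge_dir(counter, seed, target, t, budget, min_len,
                           max_len, max_paths)
  if (length(fwd) > 0) return(fwd)
  rev <- oracle_bridge_dir(counter, oracle_revcomp(target),
                           oracle_revcomp(seed), t, budget, min_len,
                           max_len, max_paths)
  vapply(rev, oracle_revcomp, character(1), USE.NAMES = FALSE)
}

# Exhaustive extension enumeration: maximal paths, recorded on reaching
# max_len or dying at >= min_len.
oracle_extend <- function(reads, seed, t, budget, min_len, max_len,
                          direction = "tail", max_paths = 1000) {
  counter <- make_counter(reads)
  k <- nchar(seed)
  start <- if (direction == "head") oracle_revcomp(seed) else seed
  paths <- character(0)
  done <- FALSE
  rec <- function(seq) {
    if (done) return()
    len <- nchar(seq)
    if (len >= max_len) {
      paths[[length(paths) + 1]] <<- seq
      if (length(paths) >= max_paths) done <<- TRUE
      return()
    }
    ctx <- substr(seq, len - k + 2, len)
    succ <- paste0(ctx, c("A", "C", "G", "T"))
    cnt <- vapply(succ, counter, numeric(1))
    ok <- cnt >= t
    if (!any(ok)) {
      if (len >= min_len) {
        paths[[length(paths) + 1]] <<- seq
        if (length(paths) >= max_paths) done <<- TRUE
      }
      return()
    }
    if (sum(ok) >= 2) {
      budget <<- budget - 1
      if (budget < 0) { done <<- TRUE; return() }
    }
    for (b in which(ok)) {
      if (done) return()
      rec(paste0(seq, c("A", "C", "G", "T")[b]))
    }
  }
  rec(start)
  if (direction == "head")
    paths <- vapply(paths, oracle_revcomp, character(1), USE.NAMES = FALSE)
  paths
}

# Reads tiling a genome at roughly uniform depth.
tile_reads <- function(genome, read_len, step = 1) {
  n <- nchar(genome)
  starts <- seq(1, max(1, n - read_len + 1), by = step)
  substring(genome, starts, pmin(starts + read_len - 1, n))
}
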