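---
title: "Hybrid long-read error correction over an FM-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid long-read error correction over an FM-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule long reads (PacBio-style) carry 10–20% errors, most of
them insertions and deletions, which cripples downstream assembly and
variant calling.  Short reads from the same sample are far more accurate
(<1%, almost all substitutions) but too short to resolve repeats on their
own.  Hybrid correction uses the short reads as a statistical model of the
underlying genome to repair the long reads.

`lrbridge` implements a de Bruijn graph–based hybrid corrector in which
the graph is never built explicitly.  Instead, the short reads are stored
as a multi-string Burrows–Wheeler transform (BWT), and an FM-index over
that BWT answers the frequency of *any* k-mer in O(k) rank steps, for any
k, on both strands.  Because node and edge membership are decided by
frequency queries at run time, the single index simultaneously represents
every k-mer de Bruijn graph of the dataset, pruned at any threshold — no
k or pruning cutoff is baked in at construction time.

## The correction model

For one long read and one k-mer size, correction proceeds as follows.

1. **Classification.**  Every k-mer of the read is looked up in the index
   (forward plus reverse-complement frequencies, always summed).  A k-mer
   with frequency at or above a threshold *t* is *solid*; strictly below,
   *weak*.  Maximal runs form solid and weak regions.
2. **Dynamic threshold.**  *t* is per-read: frequencies at or above the
   absolute floor `T` enter a list whose median is the read's median solid
   frequency *m*; then `t = max(T, ceiling(F * m))`.  On low-coverage data
   the `F * m` term vanishes and `t = T`; on deep data *t* scales with the
   read's own coverage, at any k-mer size, with no user retuning.
3. **Repair.**  A weak region flanked by two solid regions is repaired by
   *seed-and-bridge*: a depth-first traversal from the closest solid k-mer
   on the left toward the closest solid k-mer on the right, following
   (k−1)-overlap edges whose k-mers pass *t*, in A<C<G<T order.  If the
   forward traversal finds nothing, it is retried from the reverse
   complement of the target toward the reverse complement of the seed —
   branching concentrated near the seed is cheap to traverse from the far
   side.  A weak region at the read head or tail has one anchor only and
   is repaired by *seed-and-extend* in the appropriate direction.  A read
   that is weak everywhere has no anchor and passes through unchanged.
4. **Selection.**  Candidate paths are compared with the original read
   segment spanning the same anchors and the smallest Levenshtein distance
   wins (ties: larger minimum interior frequency, then lexicographic).
   No candidates means no change — every failure mode degrades to the
   identity.
5. **Branch budget.**  Each traversal charges one unit at every expanded
   node with two or more qualifying successors against a budget
   `L = B * k`; exceeding it aborts the traversal with whatever complete
   paths were already found.  This bounds worst-case work in repeat
   tangles.

The driver runs this procedure twice per read: first with a short k-mer
(`k`, default 21), which fixes the bulk of isolated sequencing errors,
then with a long K-mer (`K`, default 59) on the intermediate result.  The
long pass re-derives *t* and *L* and resolves regions that are ambiguous
at small k — two genomic loci sharing a stretch of at least k bases merge
in the k-mer graph but separate again once K exceeds the shared length.
Setting `K` to 0/`NULL` disables the second pass.

## Parameters

| name | default | meaning |
|------|---------|---------|
| `k`  | 21      | short-pass k-mer size (bases) |
| `K`  | 59      | long-pass K-mer size (bases); 0 disables |
| `T`  | 5       | absolute minimum solid frequency (counts, both strands summed) |
| `F`  | 0.10    | fraction of the per-read median solid frequency |
| `B`  | 4       | branch limit factor; per-pass budget `L = B * k` |

Counting both strands means a reverse-complement-palindromic k-mer counts
its occurrences twice; the rule is applied unconditionally so thresholds
absorb the doubling uniformly.

## Numerical and design choices

* **Median list inclusivity.**  Frequencies equal to `T` enter the median
  list (`strict_median = TRUE` switches to strictly-greater).  Inclusive
  keeps `t = T` exactly when all solid counts equal `T`.
* **Integerisation.**  `ceiling(F * m)`: counts are integers and the
  ceiling keeps the threshold conservative.
* **Path-length slack.**  For a weak-region replacement expected to span
  E bases, traversals accept lengths in `[max(k, floor(0.5 E)),
  ceiling(1.5 E) + k]`.  Indel-dominated long-read error makes
  exact-length bridges wrong; the slack is generous in both directions.
* **End-region trimming.**  Extension paths stop at a length bound, not
  at an anchor, so each candidate is trimmed to the prefix (tail) or
  suffix (head) that best fits the original segment before distances are
  compared.  A path that was consumed in full yet is still shorter than
  the original segment died inside the weak region (typically over a
  local coverage dip at large K); it is rejected outright, because
  accepting it would clip bases off the read end, and the corrector never
  trims or clips reads.
* **Branch accounting.**  The budget unit is a node expansion with ≥ 2
  qualifying successors; at most 10 complete paths are retained per
  traversal, first-found in deterministic DFS order.
* **Terminator order.**  In the multi-string BWT, `$` sorts before all
  bases and ties among terminators break by string index; k-mer counts are
  invariant to this rule, fixing it just makes construction deterministic.
* **`N` handling.**  `N` is a real alphabet symbol (self-complementary),
  so N-containing k-mers are countable, but traversals only ever propose
  A/C/G/T, keeping corrections unambiguous.  All input is uppercased.
* **Degenerate inputs.**  Reads shorter than k, reads with no weak
  region, and weak regions with no anchors or no candidates all return
  the input unchanged; an empty read collection yields an empty BWT with
  zero strings.

## The synthetic data generator

`sim_profile()` / `simulate_reads()` emulate a small bacterial-scale
experiment: a uniform-random genome carrying planted exact repeat copies
(default 50 kb with two copies of a 500 bp repeat); substitution-only
short reads (default 100 bp at 50×, 0.5% error) sampled from the genome
treated as circular, as bacterial chromosomes are — this also avoids
artificial coverage ramps at linear sequence tips; and long reads
(default 4 kb at 20×, 15% error at sub:ins:del = 1:5:4, an
indel-dominated profile typical of raw single-molecule data) sampled
linearly, each with a truth record (origin interval, strand, per-base
edit trace) so that scoring never needs an external aligner.

What the generator does **not** model: non-uniform coverage and GC bias,
error clustering and homopolymer-length effects, chimeric and
adapter-bearing reads, inexact (diverged) repeats, diploidy.  Tests
passing on this generator therefore demonstrate the correctness of the
index, traversal and selection machinery and the end-to-end behaviour of
the corrector under idealised sampling — not performance on real
instrument data.

## Evaluation

`score_correction()` aligns each original and corrected read to its known
origin interval by global unit-cost edit-distance alignment (an adaptive
banded implementation whose band doubles whenever the optimal traceback
touches the band edge, so the result equals the full-matrix optimum).
Every *reference* locus is classified before and after correction:
correct iff it aligns to exactly one matching read nucleotide; mismatched
or deleted loci are incorrect; read insertions consume no reference
locus.  Aggregated over reads:

* sensitivity = TP / (TP + FN)
* specificity = TN / (TN + FP)
* gain = (TP − FP) / (TP + FN) — the net fraction of input errors
  removed; negative if correction does more harm than good.

A zero-length corrected read counts all its origin loci as FN.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default study conditions above (50 kb genome, 25,000 short reads, 250
long reads); one simulate–index–correct–score cycle takes on the order of
a minute on a single core.  Unit tests use much smaller engineered
fixtures (≤ 2 kb) where exhaustive enumeration on an explicit de Bruijn
graph is feasible as an independent oracle.

## Known limitations

* The FM-index lives in memory and is rebuilt from the run-length-encoded
  BWT rather than serialised (construction is fast relative to loading).
* BWT construction is a direct suffix sort: simple and exact, fine for
  tens of millions of bases, not engineered for multi-gigabase datasets.
* The on-disk run-length dialect (3-bit symbol + 5-bit length chunks,
  little-endian continuation) is this package's own documented format;
  compatibility with external tools' files is best-effort only.
* Qualities are dropped: corrected bases have no meaningful quality, so
  output is always FASTA.

## A minimal session

```{r example}
library(lrbridge)

profile <- sim_profile(genome_length = 10000, long_coverage = 5, seed = 42)
ds <- simulate_reads(profile)

bwt <- build_msbwt(ds$short_reads)
fm <- build_fm_index(bwt)

corrected <- correct_reads(ds$long_reads, fm, correction_params())
score_correction(ds$long_reads, corrected, ds$truth, ds$genome)
```
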