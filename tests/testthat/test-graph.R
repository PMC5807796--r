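# Fixtures are small read sets tiling engineered genomes; expectations
# come from exhaustive enumeration on an explicitly materialised de
# Bruijn graph (helper-oracles.R).

test_that("solidity is at-threshold inclusive: weak means strictly below t", {
  fm <- build_fm_index(build_msbwt(rep("ACGTA", 5)))
  cnt <- count_kmer(fm, "ACGT") # some known positive count
  expect_true(is_solid(fm, "ACGT", cnt))
  expect_false(is_solid(fm, "ACGT", cnt + 1))
  expect_false(is_solid(fm, "GGGG", 1)) # count 0 is weak at any t >= 1
  expect_error(is_solid(fm, "ACGT", 0), "t >= 1")
})

test_that("a unique linear genome yields exactly its own bridge", {
  g <- "ACGTACCTGA"
  reads <- tile_reads(g, 6)
  fm <- build_fm_index(build_msbwt(reads))
  got <- bridge_paths(fm, "ACGT", "CTGA", t = 1, branch_limit = 100,
                      min_length = 5, max_length = 12)
  expect_identical(got$sequence, g)
  expect_identical(got$sequence,
                   oracle_bridge(reads, "ACGT", "CTGA", 1, 100, 5, 12))
  # every k-mer along the path re-validates against count_kmer
  kmers <- substring(g, 1:(nchar(g) - 3), 4:nchar(g))
  expect_true(all(count_kmer(fm, kmers) >= 1))
  expect_equal(got$min_interior_frequency, min(count_kmer(fm, kmers)))
})

test_that("seed equal to target admits the trivial path", {
  reads <- tile_reads("ACGTACCTGA", 6)
  fm <- build_fm_index(build_msbwt(reads))
  got <- bridge_paths(fm, "ACGT", "ACGT", t = 1, branch_limit = 10,
                      min_length = 4, max_length = 4)
  expect_identical(got$sequence, "ACGT")
})

test_that("the branch budget aborts traversals that need more branching", {
  # two successive two-way branch points between seed and target: every
  # bridge crosses both, so branch_limit 1 must come home empty-handed
  set.seed(1)
  s <- rand_dna(12)
  mid <- rand_dna(12)
  tg <- rand_dna(12)
  b1 <- c(rand_dna(8), rand_dna(8))
  b2 <- c(rand_dna(8), rand_dna(8))
  variants <- as.matrix(expand.grid(b1, b2))
  genomes <- apply(variants, 1, function(v) paste0(s, v[1], mid, v[2], tg))
  reads <- unlist(lapply(genomes, tile_reads, read_len = 16))
  fm <- build_fm_index(build_msbwt(reads))
  seed <- substr(s, 6, 12)
  target <- substr(tg, 1, 7)
  lens <- nchar(genomes[1])
  capped <- bridge_paths(fm, seed, target, t = 1, branch_limit = 1,
                         min_length = 7, max_length = lens)
  expect_equal(nrow(capped), 0)
  expect_true(attr(capped, "exhausted"))
  roomy <- bridge_paths(fm, seed, target, t = 1, branch_limit = 500,
                        min_length = 7, max_length = lens)
  expect_equal(sort(roomy$sequence),
               sort(oracle_bridge(reads, seed, target, 1, 500, 7, lens)))
  expect_equal(nrow(roomy), 4)
})

test_that("traversals agree with exhaustive enumeration on random fixtures", {
  set.seed(408)
  for (rep in 1:8) {
    g <- rand_dna(120)
    reads <- tile_reads(g, 25, step = 3)
    fm <- build_fm_index(build_msbwt(reads))
    k <- sample(c(6, 9), 1)
    i <- sample(10:30, 1)
    j <- nchar(g) - sample(30:45, 1) - k + 1
    seed <- substr(g, i, i + k - 1)
    target <- substr(g, j, j + k - 1)
    # anchors must be solid at the threshold in force (precondition)
    if (!all(is_solid(fm, c(seed, target), 2))) next
    span <- j + k - i
    got <- bridge_paths(fm, seed, target, t = 2, branch_limit = 1000,
                        min_length = floor(span / 2),
                        max_length = span * 2, max_paths = 1000)
    want <- oracle_bridge(reads, seed, target, 2, 1000, floor(span / 2),
                          span * 2)
    expect_identical(got$sequence, want)
    # every returned path re-validates k-mer by k-mer
    for (p in got$sequence) {
      kmers <- substring(p, 1:(nchar(p) - k + 1), k:nchar(p))
      expect_true(all(count_kmer(fm, kmers) >= 2))
    }
  }
})

test_that("raising the threshold never yields additional paths", {
  set.seed(409)
  g <- rand_dna(150)
  reads <- c(tile_reads(g, 30, step = 2), tile_reads(g, 30, step = 5))
  fm <- build_fm_index(build_msbwt(reads))
  seed <- substr(g, 1, 8)
  target <- substr(g, 143, 150)
  n_prev <- Inf
  for (t in c(1, 2, 4, 8, 16)) {
    got <- bridge_paths(fm, seed, target, t = t, branch_limit = 1000,
                        min_length = 10, max_length = 300,
                        max_paths = 1000)
    expect_lte(nrow(got), n_prev)
    n_prev <- nrow(got)
  }
})

test_that("a repeat ambiguous at small k resolves at large K", {
  set.seed(410)
  rep_unit <- rand_dna(20)
  a <- rand_dna(50); b <- rand_dna(50); c <- rand_dna(50)
  g <- paste0(a, rep_unit, b, rep_unit, c)
  reads <- tile_reads(g, 80, step = 2)
  fm <- build_fm_index(build_msbwt(reads))
  lims <- c(floor(nchar(g) / 2), ceiling(1.5 * nchar(g)) + 31)
  small <- bridge_paths(fm, substr(g, 1, 11), substr(g, 180, 190),
                        t = 1, branch_limit = 4 * 11,
                        min_length = lims[1], max_length = lims[2],
                        max_paths = 1000)
  big <- bridge_paths(fm, substr(g, 1, 31), substr(g, 160, 190),
                      t = 1, branch_limit = 4 * 31,
                      min_length = lims[1], max_length = lims[2],
                      max_paths = 1000)
  expect_gt(nrow(small), 1) # the short k-mer graph merges the two copies
  expect_identical(big$sequence, g) # the long K-mer graph does not
  expect_identical(sort(small$sequence),
                   sort(oracle_bridge(reads, substr(g, 1, 11),
                                      substr(g, 180, 190), 1, 44,
                                      lims[1], lims[2])))
})

test_that("extensions return maximal in-bound paths and honor direction", {
  g <- "ACGTACCTGATTGCA"
  reads <- tile_reads(g, 8)
  fm <- build_fm_index(build_msbwt(reads))
  tail <- extend_paths(fm, "ACGT", t = 1, branch_limit = 100,
                       min_length = 10, max_length = nchar(g),
                       direction = "tail")
  expect_identical(tail$sequence,
                   oracle_extend(reads, "ACGT", 1, 100, 10, nchar(g)))
  expect_true(g %in% tail$sequence)
  head <- extend_paths(fm, "TGCA", t = 1, branch_limit = 100,
                       min_length = 10, max_length = nchar(g),
                       direction = "head")
  expect_identical(head$sequence,
                   oracle_extend(reads, "TGCA", 1, 100, 10, nchar(g),
                                 direction = "head"))
  expect_true(g %in% head$sequence)
})

test_that("dead ends shorter than the minimum length are discarded", {
  reads <- tile_reads("ACGGACTT", 5)
  fm <- build_fm_index(build_msbwt(reads))
  # the seed is the genome's last 5-mer: no solid successor on either strand
  got <- extend_paths(fm, "GACTT", t = 1, branch_limit = 10,
                      min_length = 10, max_length = 30)
  expect_equal(nrow(got), 0)
})

test_that("head and tail extension are strand-mirrored", {
  set.seed(411)
  g <- rand_dna(60)
  reads <- tile_reads(g, 20, step = 2)
  fm <- build_fm_index(build_msbwt(reads))
  seed <- substr(g, 1, 8)
  tail <- extend_paths(fm, seed, t = 1, branch_limit = 200,
                       min_length = 20, max_length = 60)
  head <- extend_paths(fm, revcomp(seed), t = 1, branch_limit = 200,
                       min_length = 20, max_length = 60,
                       direction = "head")
  expect_identical(sort(revcomp(head$sequence)), sort(tail$sequence))
})

test_that("reverse bridging rescues budget exhaustion near the seed", {
  # a branchy "trap" subgraph hangs off the node right after the seed and
  # is explored first (its edges sort before the true one); with a tight
  # budget the forward traversal exhausts inside the trap.  From the
  # reverse complement of the target the trap edges point the other way,
  # so the retry finds the bridge and flips it back.
  set.seed(4)
  main <- rand_dna(60)
  pre <- substr(main, 1, 14)
  combos <- expand.grid(c("AA", "CC"), c("AA", "CC"), c("AA", "CC"))
  traps <- apply(combos, 1,
                 function(v) paste0(pre, "A", paste(v, collapse = "")))
  reads <- c(tile_reads(main, 16),
             unlist(lapply(traps, tile_reads, read_len = 16)))
  fm <- build_fm_index(build_msbwt(reads))
  seed <- substr(main, 8, 14)
  target <- substr(main, 54, 60)
  expect_false(substr(main, 15, 15) == "A") # trap really sorts first
  fwd <- oracle_bridge_dir(make_counter(reads), seed, target,
                           t = 1, budget = 3, min_len = 7, max_len = 90)
  expect_length(fwd, 0)
  got <- bridge_paths(fm, seed, target, t = 1, branch_limit = 3,
                      min_length = 7, max_length = 90)
  expect_true(attr(got, "reversed"))
  expect_identical(got$sequence, substr(main, 8, 60)) # seed through target
})
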