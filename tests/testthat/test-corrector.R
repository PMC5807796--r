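# A deeply covered unique genome plus targeted corruptions; the genome
# substring is always the known truth.

make_index <- function(genome, read_len = 30, step = 1) {
  build_fm_index(build_msbwt(tile_reads(genome, read_len, step)))
}

test_that("the dynamic threshold follows max(T, ceiling(F * median))", {
  expect_equal(dynamic_threshold(rep(50, 11), T = 5, F = 0.10), 5)
  expect_equal(dynamic_threshold(c(1, 2, 3, 4), T = 5, F = 0.10), 5)
  expect_equal(dynamic_threshold(c(10, 20, 100), T = 5, F = 0.5), 10)
  # frequencies below T never enter the median list
  expect_equal(dynamic_threshold(c(1, 1, 1, 100), T = 5, F = 0.5), 50)
  # ceiling integerises upward
  expect_equal(dynamic_threshold(c(101), T = 5, F = 0.1), 11)
  # inclusive vs strict median list
  expect_equal(dynamic_threshold(c(5, 5, 5), T = 5, F = 1), 5)
  expect_equal(dynamic_threshold(c(5, 5, 5), T = 5, F = 1, strict = TRUE), 5)
  expect_equal(dynamic_threshold(c(5, 5, 9), T = 5, F = 1, strict = TRUE), 9)
  expect_equal(dynamic_threshold(numeric(0), T = 3, F = 0.9), 3)
  expect_error(dynamic_threshold(1:3, T = 0), "T")
  expect_error(dynamic_threshold(1:3, T = 5, F = 2), "F")
})

test_that("segmentation tiles the k-mer positions into alternating regions", {
  set.seed(412)
  g <- rand_dna(400)
  fm <- make_index(g)
  k <- 15
  # clean read: one solid region
  read <- substr(g, 51, 250)
  seg <- classify_and_segment(read, k, fm, t = 2)
  expect_identical(seg$kind, "solid")
  expect_equal(seg$start, 0L)
  expect_equal(seg$end, nchar(read) - k + 1L)
  # one substitution in the middle: solid, weak, solid
  pos <- 100L
  bad <- read
  substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read, pos, pos))[1]
  seg2 <- classify_and_segment(bad, k, fm, t = 2)
  expect_identical(seg2$kind, c("solid", "weak", "solid"))
  expect_equal(seg2$start[2], pos - k) # 0-based k-mer index pos-1-k+1
  expect_equal(seg2$end[2], pos)
  # regions tile without overlap and alternate
  expect_equal(seg2$start[-1], seg2$end[-3])
  # random read: everything weak
  seg3 <- classify_and_segment(rand_dna(120), k, fm, t = 2)
  expect_identical(seg3$kind, "weak")
  # read shorter than k: no regions
  expect_equal(nrow(classify_and_segment("ACGT", k, fm, t = 2)), 0)
})

test_that("an internal weak region is bridged back to the truth", {
  set.seed(413)
  g <- rand_dna(500)
  fm <- make_index(g)
  k <- 15
  read <- substr(g, 101, 350)
  bad <- read
  substr(bad, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read, 120, 120))[1]
  seg <- classify_and_segment(bad, k, fm, t = 2)
  w <- seg[seg$kind == "weak", ]
  fix <- repair_region(bad, fm, k, t = 2, branch_limit = 4 * k,
                       weak_start = w$start, weak_end = w$end)
  patched <- paste0(substr(bad, 1, fix$start), fix$replacement,
                    substr(bad, fix$end + 1, nchar(bad)))
  expect_identical(patched, read)
})

test_that("a fully weak read is left untouched", {
  set.seed(414)
  fm <- make_index(rand_dna(300))
  read <- rand_dna(100)
  expect_identical(correct_read(read, correction_params(k = 15, K = 21), fm),
                   read)
})

test_that("candidate selection minimises edit distance with stable ties", {
  # two parallel mid-segments between shared anchors; the read's segment
  # is one substitution away from variant 1 and further from variant 2
  set.seed(415)
  s <- rand_dna(20)
  tg <- rand_dna(20)
  m1 <- rand_dna(12)
  m2 <- paste0(substr(m1, 1, 4), rand_dna(4), substr(m1, 9, 12))
  g1 <- paste0(s, m1, tg)
  g2 <- paste0(s, m2, tg)
  reads <- c(tile_reads(g1, 20), tile_reads(g2, 20))
  fm <- build_fm_index(build_msbwt(reads))
  k <- 10
  mut <- m1
  substr(mut, 6, 6) <- setdiff(c("A", "C", "G", "T"), substr(m1, 6, 6))[1]
  read <- paste0(s, mut, tg)
  seg <- classify_and_segment(read, k, fm, t = 2)
  w <- seg[seg$kind == "weak", ]
  fix <- repair_region(read, fm, k, t = 2, branch_limit = 100,
                       weak_start = w$start[1], weak_end = w$end[1])
  original <- substr(read, fix$start + 1, fix$end)
  # the replacement must beat or match every candidate under an
  # independent Levenshtein implementation
  cands <- bridge_paths(fm, substr(read, fix$start + 1, fix$start + k),
                        substr(read, fix$end - k + 1, fix$end),
                        t = 2, branch_limit = 100,
                        min_length = k, max_length = nchar(original) * 2)
  d <- utils::adist(cands$sequence, original)[, 1]
  expect_equal(utils::adist(fix$replacement, original)[1, 1], min(d))
  expect_true(grepl(m1, fix$replacement, fixed = TRUE))
})

test_that("single-pass correction recovers point errors and respects identity", {
  set.seed(416)
  g <- rand_dna(600)
  fm <- make_index(g)
  params <- correction_params(k = 15, K = 25, T = 2)
  clean <- substr(g, 101, 400)
  expect_identical(correct_pass(clean, 15, params, fm), clean)
  expect_identical(correct_read(clean, params, fm), clean)
  expect_identical(correct_read("ACG", params, fm), "ACG") # shorter than k
  # substitution, insertion, deletion each recovered
  sub <- clean; substr(sub, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                                 substr(clean, 150, 150))[1]
  expect_identical(correct_read(sub, params, fm), clean)
  ins <- paste0(substr(clean, 1, 150), "A", substr(clean, 151, 300))
  expect_identical(correct_read(ins, params, fm), clean)
  del <- paste0(substr(clean, 1, 149), substr(clean, 151, 300))
  expect_identical(correct_read(del, params, fm), clean)
  # errors at the read head and tail are repaired by extension
  head_err <- clean; substr(head_err, 4, 4) <-
    setdiff(c("A", "C", "G", "T"), substr(clean, 4, 4))[1]
  expect_identical(correct_read(head_err, params, fm), clean)
  tail_err <- clean; substr(tail_err, 297, 297) <-
    setdiff(c("A", "C", "G", "T"), substr(clean, 297, 297))[1]
  expect_identical(correct_read(tail_err, params, fm), clean)
})

test_that("omitting K reduces the driver to a single short-k pass", {
  set.seed(417)
  g <- rand_dna(400)
  fm <- make_index(g)
  p1 <- correction_params(k = 15, K = NULL, T = 2)
  read <- substr(g, 51, 250)
  substr(read, 80, 80) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, 80, 80))[1]
  expect_identical(correct_read(read, p1, fm),
                   correct_pass(read, 15, p1, fm))
  expect_identical(correction_params(K = 0)$K, NULL)
  expect_error(correction_params(k = 21, K = 21), "smaller than K")
})

test_that("read correction is independent, order-preserving and parallel-safe", {
  set.seed(418)
  g <- rand_dna(800)
  fm <- make_index(g)
  params <- correction_params(k = 15, K = 25, T = 2)
  reads <- vapply(1:12, function(i) {
    s <- sample(500, 1)
    r <- substr(g, s, s + 200)
    substr(r, 100, 100) <- sample(c("A", "C", "G", "T"), 1)
    r
  }, character(1))
  names(reads) <- sprintf("r%02d", 1:12)
  once <- correct_reads(reads, fm, params)
  again <- correct_reads(reads, fm, params)
  expect_identical(once, again)
  par4 <- correct_reads(reads, fm, params, processes = 4)
  expect_identical(once, par4)
  expect_identical(names(once), names(reads))
  # permuting the input permutes the output identically
  perm <- sample(12)
  expect_identical(correct_reads(reads[perm], fm, params), once[perm])
})
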