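test_that("planted families are recovered exactly", {
  gt <- make_genome(small_genome_spec(seed = 17L))
  fams <- find_repeat_families(gt$genome, min_length = 50L)
  expect_length(fams, 1L)
  fam <- fams[[1L]]
  expect_equal(fam$core_length, 1362L)
  expect_equal(fam$n_copies, 6L)
  expect_setequal(fam$copies$start, gt$truth$repeat_copy_intervals$start)
  expect_true(all(fam$copies$orientation == "direct"))
})

test_that("detection agrees with a brute-force scan on small genomes", {
  for (seed in c(2L, 9L)) {
    gt <- make_genome(genome_spec(n_repeats = 3L, core_length = 150L,
                                  extension_left = c(0L, 10L, 25L),
                                  extension_right = c(0L, 12L, 30L),
                                  singlecopy_lengths = rep(400L, 3L),
                                  seed = seed))
    fams <- find_repeat_families(gt$genome, min_length = 20L)
    oracle <- oracle_longest_repeat(gt$genome$seq, min_length = 20L)
    fam <- fams[[1L]]
    # the oracle's longest duplicated substring is the pair-maximal repeat:
    # core plus the longest extension shared by at least two copies
    fam <- compute_extensions(gt$genome, fam)
    both <- fam$left_extension + fam$right_extension
    pairmax <- fam$core_length + max(both, na.rm = TRUE)
    expect_equal(oracle$length, pairmax)
    # every oracle occurrence lies inside a detected family's territory
    for (p in oracle$positions) {
      inside <- any(vapply(seq_len(fam$n_copies), function(i)
        mitodyn:::circ_intervals_overlap(
          p, p + oracle$length,
          fam$copies$start[i] - max(fam$left_extension, na.rm = TRUE),
          fam$copies$end[i] + max(fam$right_extension, na.rm = TRUE),
          gt$genome$length), TRUE))
      expect_true(inside)
    }
  }
})

test_that("unrepeated genomes and short genomes yield no families", {
  g <- structure(list(name = "r", seq = mitodyn:::random_dna(10000L),
                      length = 10000L, circular = TRUE),
                 class = "circular_genome")
  set.seed(1)
  expect_length(find_repeat_families(g, min_length = 100L), 0L)
  tiny <- structure(list(name = "t", seq = "ACGTACG", length = 7L,
                         circular = TRUE), class = "circular_genome")
  expect_length(find_repeat_families(tiny, min_length = 8L), 0L)
  expect_error(find_repeat_families(g, min_length = 4L), ">= 8")
})

test_that("low-complexity families are flagged and filtered by default", {
  g <- structure(list(name = "poly", seq = strrep("A", 500L), length = 500L,
                      circular = TRUE), class = "circular_genome")
  expect_length(find_repeat_families(g, min_length = 50L), 0L)
  raw <- find_repeat_families(g, min_length = 50L, low_complexity_filter = FALSE)
  expect_gte(length(raw), 1L)
  expect_true(raw[[1L]]$low_complexity)
})

test_that("extension matrices equal the planted ground truth", {
  spec <- small_genome_spec(seed = 23L)
  gt <- make_genome(spec)
  fam <- compute_extensions(gt$genome, find_repeat_families(gt$genome, 50L)[[1L]])
  ord <- order(fam$copies$start)   # genome order = planted copy order
  extL <- gt$truth$extension_left
  extR <- gt$truth$extension_right
  wantL <- outer(extL, extL, pmin); diag(wantL) <- NA_integer_
  wantR <- outer(extR, extR, pmin); diag(wantR) <- NA_integer_
  expect_identical(fam$left_extension[ord, ord], wantL)
  expect_identical(fam$right_extension[ord, ord], wantR)
})

test_that("extensions satisfy the nested-subset (ultrametric-like) property", {
  gt <- make_genome(small_genome_spec(seed = 31L))
  fam <- compute_extensions(gt$genome, find_repeat_families(gt$genome, 50L)[[1L]])
  m <- fam$left_extension
  n <- nrow(m)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (length(unique(c(i, j, k))) < 3L) next
    expect_gte(m[i, k], min(m[i, j], m[j, k]))
  }
})

test_that("fully distinct flanks give all-zero extensions", {
  gt <- make_genome(genome_spec(n_repeats = 3L, core_length = 200L,
                                extension_left = c(0L, 0L, 0L),
                                extension_right = c(0L, 0L, 0L),
                                singlecopy_lengths = rep(500L, 3L), seed = 2L))
  fam <- compute_extensions(gt$genome, find_repeat_families(gt$genome, 50L)[[1L]])
  expect_true(all(fam$left_extension[upper.tri(fam$left_extension)] == 0L))
  expect_true(all(fam$right_extension[upper.tri(fam$right_extension)] == 0L))
})

test_that("flanks identical across all copies re-extend the family core", {
  gt <- make_genome(genome_spec(n_repeats = 2L, core_length = 300L,
                                extension_left = c(0L, 0L),
                                extension_right = c(0L, 0L),
                                singlecopy_lengths = rep(600L, 2L), seed = 4L))
  fam <- find_repeat_families(gt$genome, 50L)[[1L]]
  # pretend the detected core had missed 25 nt on each copy's 3' side
  short <- fam
  short$core_length <- fam$core_length - 25L
  short$copies$end <- fam$copies$end - 25L
  expect_warning(fixed <- compute_extensions(gt$genome, short), "re-extending")
  expect_equal(fixed$core_length, fam$core_length)
  expect_equal(fixed$copies$start, fam$copies$start)
})

test_that("overlapping copies are rejected", {
  gt <- make_genome(small_genome_spec(seed = 3L, n = 2L, core = 300L))
  fam <- find_repeat_families(gt$genome, 50L)[[1L]]
  fam$copies$start[2L] <- fam$copies$start[1L] + 10L
  fam$copies$end[2L] <- fam$copies$end[1L] + 10L
  expect_error(compute_extensions(gt$genome, fam), "overlap")
})
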