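test_that("make_genome plants exactly the specified repeat structure", {
  spec <- small_genome_spec(seed = 3L)
  gt <- make_genome(spec)
  g <- gt$genome; tr <- gt$truth

  expect_s3_class(g, "circular_genome")
  expect_equal(g$length, nchar(g$seq))
  expect_equal(g$length, 6L * 1362L + 6L * 600L)

  # all copies identical, direct orientation
  copies <- vapply(seq_len(6), function(i)
    substr(g$seq, tr$repeat_copy_intervals$start[i] + 1L,
           tr$repeat_copy_intervals$end[i]), "")
  expect_length(unique(copies), 1L)
  expect_equal(nchar(copies[1L]), 1362L)

  # planted enzyme sites and no others
  occ <- mitodyn:::circ_occurrences(g$seq, tr$enzyme_site)
  expect_identical(occ, tr$site_positions)

  # annotations tile the genome: cores + single-copy regions cover it
  ci <- tr$repeat_copy_intervals; si <- tr$singlecopy_intervals
  expect_equal(sum(ci$end - ci$start) + sum(si$end - si$start), g$length)
})

test_that("seeded generation is byte-identical and seeds matter", {
  a <- make_genome(small_genome_spec(seed = 7L, n = 3L, core = 200L))
  b <- make_genome(small_genome_spec(seed = 7L, n = 3L, core = 200L))
  c <- make_genome(small_genome_spec(seed = 8L, n = 3L, core = 200L))
  expect_identical(a$genome$seq, b$genome$seq)
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("infeasible genome specs are rejected with messages", {
  expect_error(genome_spec(n_repeats = 0L), "n_repeats")
  # extensions shared by all copies would be core
  expect_error(genome_spec(n_repeats = 3L, core_length = 100L,
                           extension_left = c(10L, 20L, 30L),
                           extension_right = c(0L, 0L, 0L),
                           singlecopy_lengths = rep(500L, 3L)),
               "absorbed into the core")
  # extensions exceeding the single-copy region (both ends of one gap)
  expect_error(genome_spec(n_repeats = 2L, core_length = 100L,
                           extension_left = c(0L, 250L),
                           extension_right = c(250L, 0L),
                           singlecopy_lengths = rep(400L, 2L)),
               "unique sequence")
  # enzyme site colliding with an extension
  expect_error(genome_spec(n_repeats = 2L, core_length = 100L,
                           extension_left = c(0L, 10L),
                           extension_right = c(0L, 50L),
                           singlecopy_lengths = rep(500L, 2L),
                           site_offsets = c(20L, 20L)),
               "collides")
})

test_that("equilibrium pool enumerates one molecule per flanking pair", {
  gt <- make_genome(small_genome_spec(seed = 5L))
  pool <- make_equilibrium_molecules(gt$genome, gt$truth)
  expect_equal(nrow(pool), 36L)
  expect_equal(length(unique(pool$weight)), 1L)
  # n = 2 gives the 2x2 enumeration
  gt2 <- make_genome(small_genome_spec(seed = 5L, n = 2L, core = 300L))
  pool2 <- make_equilibrium_molecules(gt2$genome, gt2$truth)
  expect_equal(nrow(pool2), 4L)
  expect_equal(data.frame(pool2[, c("left_id", "right_id")]),
               data.frame(left_id = rep(1:2, each = 2L), right_id = rep(1:2, 2L)))
  # weights on the reference pairs only reproduce the master circle
  w <- matrix(0, 6, 6); diag(w) <- 1
  ref_pool <- make_equilibrium_molecules(gt$genome, gt$truth, weights = w)
  expect_true(all((ref_pool$weight > 0) == (ref_pool$left_id == ref_pool$right_id)))
  expect_error(make_equilibrium_molecules(gt$genome, gt$truth,
                                          weights = matrix(0, 6, 6)),
               "zero")
})

test_that("molecule sequences are genuine junction sequences", {
  gt <- make_genome(small_genome_spec(seed = 5L))
  pool <- make_equilibrium_molecules(gt$genome, gt$truth, span = 400L)
  tr <- gt$truth; g <- gt$genome; L <- g$length
  for (r in c(1L, 8L, 36L)) {
    i <- pool$left_id[r]; j <- pool$right_id[r]
    P <- tr$repeat_copy_intervals$start
    E <- tr$repeat_copy_intervals$end
    want <- paste0(
      mitodyn:::circ_substr(g$seq, (P[i] - 400L) %% L, (P[i] - 400L) %% L + 400L),
      mitodyn:::circ_substr(g$seq, P[i], E[i]),
      mitodyn:::circ_substr(g$seq, E[j] %% L, E[j] %% L + 400L))
    expect_identical(pool$seq[r], want)
  }
})

test_that("read pairs have the documented count, geometry, and determinism", {
  gt <- make_genome(genome_spec(seed = 21L))
  pool <- make_equilibrium_molecules(gt$genome, gt$truth)
  rp <- make_read_pairs(pool, coverage = 7, seed = 2L)
  expect_equal(nrow(rp), round(7 * gt$genome$length / mean(c(4000, 6500))))
  expect_true(all(rp$insert >= 4000L & rp$insert <= 6500L))
  expect_true(all(nchar(rp$read1) == 700L & nchar(rp$read2) == 700L))
  # reads are faithful molecule substrings (read2 reverse-complemented)
  i <- 5L
  mol <- pool$seq[rp$molecule[i]]
  expect_identical(rp$read1[i], substr(mol, rp$start[i] + 1L, rp$start[i] + 700L))
  expect_identical(mitodyn:::revcomp(rp$read2[i]),
                   substr(mol, rp$start[i] + rp$insert[i] - 699L,
                          rp$start[i] + rp$insert[i]))
  expect_identical(rp, make_read_pairs(pool, coverage = 7, seed = 2L))
  expect_equal(nrow(make_read_pairs(pool, coverage = 0, seed = 1L)), 0L)
})

test_that("read sampling frequencies follow the pool weights", {
  gt <- make_genome(genome_spec(seed = 22L))
  pool <- make_equilibrium_molecules(gt$genome, gt$truth)
  ps <- vapply(1:20, function(s) {
    rp <- make_read_pairs(pool, coverage = 50, seed = 100L + s)
    counts <- tabulate(rp$molecule, nbins = 36L)
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }, 1)
  expect_gte(sum(ps > 0.01), 18L)
})

test_that("mutate_k places exactly k substitutions", {
  s <- make_structured_rna(118L, example_5s_structure(), seed = 4L)
  expect_identical(mutate_k(s, 0L), s)
  hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  m16 <- mutate_k(s, 16L, seed = 9L)
  expect_equal(hamming(s, m16), 16L)
  mall <- mutate_k(s, nchar(s), seed = 9L)
  expect_equal(hamming(s, mall), nchar(s))
  expect_identical(mutate_k(s, 16L, seed = 9L), m16)
  expect_error(mutate_k(s, nchar(s) + 1L), "between 0 and")
})

test_that("structured RNA respects its structure and seed", {
  st <- parse_structure(example_5s_structure())
  s <- make_structured_rna(118L, st, seed = 1L)
  v <- strsplit(s, "")[[1L]]
  for (r in seq_len(nrow(st$pairs)))
    expect_true(paste0(v[st$pairs[r, 1L]], v[st$pairs[r, 2L]]) %in%
                  c("AU", "UA", "CG", "GC", "GU", "UG"))
  expect_identical(s, make_structured_rna(118L, st, seed = 1L))
  # all-dots structure is unconstrained but reproducible
  free <- make_structured_rna(30L, strrep(".", 30L), seed = 2L)
  expect_equal(nchar(free), 30L)
  expect_error(make_structured_rna(100L, st), "does not match")
})

test_that("conversion alignments carry the planted tract", {
  aln <- make_conversion_alignment(500L, donor_divergence = 0.15,
                                   tract = c(200L, 50L),
                                   outgroup_divergence = 0.02, seed = 3L)
  r <- strsplit(aln$sequences[["recipient"]], "")[[1L]]
  d <- strsplit(aln$sequences[["donor"]], "")[[1L]]
  inside <- 201:250
  expect_equal(mean(r[inside] == d[inside]), 1.0)
  outside <- setdiff(seq_len(500L), inside)
  expect_gt(mean(r[outside] == d[outside]), 0.78)
  expect_lt(mean(r[outside] == d[outside]), 0.92)
  # zero-length tract plants no signal
  aln0 <- make_conversion_alignment(500L, 0.15, c(0L, 0L), 0.02, seed = 3L)
  r0 <- strsplit(aln0$sequences[["recipient"]], "")[[1L]]
  o0 <- strsplit(aln0$sequences[["outgroup"]], "")[[1L]]
  expect_gt(mean(r0 == o0), 0.95)
  expect_identical(aln$sequences,
                   make_conversion_alignment(500L, 0.15, c(200L, 50L), 0.02,
                                             seed = 3L)$sequences)
})

test_that("the bundled tRNA preset carries the published gene complement", {
  tr <- make_trna_set("silene_latifolia_table1")
  expect_equal(nrow(tr), 11L)
  expect_equal(sum(tr$chloroplast_origin), 5L)
  expect_equal(sum(tr$pseudogene), 2L)
  expect_equal(sum(tr$initiator), 1L)
  expect_equal(sum(tr$lysidine), 1L)
  expect_setequal(tr$anticodon[tr$name %in% c("trnI(cau)", "trnfM(cau)")], "CAU")
  expect_error(make_trna_set("no_such_preset"), "unknown")
  expect_equal(nrow(make_trna_set(data.frame())), 0L)
  one <- make_trna_set(data.frame(name = "trnE(uuc)", anticodon = "uuc",
                                  amino_acid = "Glu"))
  expect_equal(nrow(one), 1L)
  expect_identical(one$anticodon, "UUC")
})
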