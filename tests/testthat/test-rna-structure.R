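test_that("dot-bracket parsing round-trips and flags imbalance", {
  st <- parse_structure("((..))")
  expect_equal(st$pairs, matrix(c(1L, 6L, 2L, 5L), 2L, byrow = TRUE,
                                dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(parse_structure("....")$pairs), 0L)
  expect_identical(as.character(parse_structure(example_5s_structure())),
                   example_5s_structure())
  expect_error(parse_structure("(()"), "position 1")
  expect_error(parse_structure("())"), "position 3")
  expect_error(parse_structure("(a)"), "only")
})

test_that("energy of hand-decomposable structures matches direct lookup", {
  p <- default_energy_params()
  expect_equal(evaluate_energy("ACGU", "...."), 0)
  # one two-stack helix closed by a tetraloop
  e <- evaluate_energy("GGGAAAACCC", "(((....)))")
  expect_equal(e, 2 * p$stack["GC", "GC"] + unname(p$hairpin["4"]),
               tolerance = 1e-12)
  # helix - bulge - helix
  #  GG A GG AAAA CC CC : ((.((....)).))
  e2 <- evaluate_energy("GGAGGAAAACCCC", "((.((....))))")
  expect_equal(e2, p$stack["GC", "GC"] + unname(p$bulge["1"]) +
                 p$stack["GC", "GC"] + unname(p$hairpin["4"]),
               tolerance = 1e-12)
})

test_that("energy agrees with the independent recursive oracle", {
  p <- default_energy_params()
  st <- example_5s_structure()
  for (seed in 1:8) {
    s <- make_structured_rna(118L, st, seed = seed)
    expect_equal(evaluate_energy(s, st, p),
                 oracle_energy(s, st, p), tolerance = 1e-9)
  }
  # and on mutated sequences in lenient mode
  for (seed in 1:5) {
    s <- make_structured_rna(118L, st, seed = seed)
    m <- mutate_k(s, 16L, seed = seed + 50L)
    expect_equal(evaluate_energy(m, st, p, lenient = TRUE),
                 oracle_energy(m, st, p), tolerance = 1e-9)
  }
})

test_that("energy is additive over disconnected domains", {
  p <- default_energy_params()
  dbA <- "(((....)))"
  dbB <- "((((....))))"
  sA <- make_structured_rna(10L, dbA, seed = 1L)
  sB <- make_structured_rna(12L, dbB, seed = 2L)
  expect_equal(evaluate_energy(paste0(sA, "..", sB), paste0(dbA, "..", dbB), p),
               evaluate_energy(sA, dbA, p) + evaluate_energy(sB, dbB, p),
               tolerance = 1e-12)
})

test_that("invalid pairs error strictly and score leniently", {
  expect_error(evaluate_energy("GGGAAAACCA", "(((....)))"), "not a Watson-Crick")
  strict <- evaluate_energy("GGGAAAACCC", "(((....)))")
  len <- evaluate_energy("GGGAAAACCA", "(((....)))", lenient = TRUE)
  expect_gt(len, strict)   # losing a stack destabilises
})

test_that("substitution classification follows the published case anatomy", {
  db <- "((((....))))"
  ref <- "CGGC AAAA GCCG"; ref <- gsub(" ", "", ref)
  # loop substitution
  alt <- ref; substr(alt, 6L, 6L) <- "C"
  expect_equal(as.integer(classify_substitutions(ref, alt, db)$counts["loop"]), 1L)
  # C:G -> G:C with both partners substituted (positions 1 and 12)
  alt <- ref; substr(alt, 1L, 1L) <- "G"; substr(alt, 12L, 12L) <- "C"
  cc <- classify_substitutions(ref, alt, db)$counts
  expect_equal(as.integer(cc["helix_compensatory"]), 2L)
  # A:U -> G:U, partner unchanged: conservative
  ref2 <- "AGGC AAAA GCCU"; ref2 <- gsub(" ", "", ref2)
  alt2 <- ref2; substr(alt2, 1L, 1L) <- "G"
  expect_equal(as.integer(
    classify_substitutions(ref2, alt2, db)$counts["helix_conservative"]), 1L)
  # G -> A opposite C: disruptive
  alt3 <- ref; substr(alt3, 2L, 2L) <- "A"
  expect_equal(as.integer(
    classify_substitutions(ref, alt3, db)$counts["helix_disruptive"]), 1L)
  expect_error(classify_substitutions(ref, paste0(ref, "A"), db), "equal length")
})

test_that("compensatory orientation swaps leave the energy exactly unchanged", {
  st <- example_5s_structure()
  ps <- parse_structure(st)$pairs
  s <- make_structured_rna(118L, st, seed = 12L)
  v <- strsplit(s, "")[[1L]]
  for (r in c(2L, 7L, 19L, 30L)) {
    tmp <- v[ps[r, 1L]]; v[ps[r, 1L]] <- v[ps[r, 2L]]; v[ps[r, 2L]] <- tmp
  }
  swapped <- paste(v, collapse = "")
  expect_identical(evaluate_energy(s, st), evaluate_energy(swapped, st))
})

test_that("conservation test fields, conventions and errors", {
  st <- example_5s_structure()
  ref <- make_structured_rna(118L, st, seed = 2L)
  obs <- mutate_in_loops(ref, st, 16L, seed = 3L)
  ct <- conservation_test(ref, st, obs, N = 199L, seed = 4L)
  expect_equal(ct$k, 16L)
  expect_length(ct$null_dg, 199L)
  expect_gt(ct$p.value, 0)
  expect_lte(ct$p.value, 1)
  # loop-confined mutants keep the reference energy exactly
  expect_equal(ct$observed_dg, evaluate_energy(ref, st, lenient = TRUE),
               tolerance = 1e-12)
  expect_error(conservation_test(ref, st, ref, N = 99L), "identical")
  # determinism
  ct2 <- conservation_test(ref, st, obs, N = 199L, seed = 4L)
  expect_identical(ct$null_dg, ct2$null_dg)
})

test_that("energy parameters load, validate, and can be customised", {
  p <- default_energy_params()
  expect_s3_class(p, "energy_params")
  expect_equal(dim(p$stack), c(6L, 6L))
  expect_true(all(p$hairpin >= 0))
  # symmetric under reversal of both pairs (thermodynamic consistency)
  rev_pair <- function(x) paste0(substr(x, 2L, 2L), substr(x, 1L, 1L))
  for (a in rownames(p$stack)) for (b in colnames(p$stack))
    expect_equal(p$stack[a, b], p$stack[rev_pair(b), rev_pair(a)])
  # long loops extrapolate logarithmically
  expect_equal(mitodyn:::loop_penalty(p$hairpin, 40L, p$lxc),
               unname(p$hairpin["10"]) + p$lxc * log(4))
  # editable TSV round trip
  tmp <- tempfile(fileext = ".tsv")
  file.copy(system.file("extdata", "nn_energy_params.tsv", package = "mitodyn"),
            tmp)
  p2 <- read_energy_params(tmp)
  expect_equal(p2$stack, p$stack)
})
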