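decoding_grid_expected <- c(
  UAU = "wobble", UAC = "direct", UGU = "wobble", UGC = "direct",
  UGG = "direct", CAU = "wobble", CAC = "direct",
  CCU = "wobble", CCC = "wobble", CCA = "direct", CCG = "wobble",
  AAU = "wobble", AAC = "direct", AUA = "direct", AUG = "direct",
  GAA = "direct", GAG = "wobble")

test_that("wobble partners implement the expanded rules base by base", {
  g34 <- wobble_partners("G")
  expect_equal(g34$status[g34$base == "C"], "direct")
  expect_equal(g34$status[g34$base == "U"], "wobble")
  expect_equal(wobble_partners("C")$base, "G")
  lys <- wobble_partners("C", lysidine = TRUE)
  expect_equal(lys$base, "A")
  u_split <- wobble_partners("U", family_box = FALSE)
  expect_setequal(u_split$base, c("A", "G"))
  u_fam <- wobble_partners("U", family_box = TRUE)
  expect_setequal(u_fam$base, c("A", "G", "U", "C"))
  expect_equal(sum(u_fam$status == "direct"), 1L)
  expect_equal(wobble_partners("A")$base, "U")
  expect_error(wobble_partners("X"), "one of")
  expect_error(wobble_partners("G", lysidine = TRUE), "C34")
})

test_that("the bundled mitochondrial tRNA set reproduces the published decoding grid cell for cell", {
  tab <- build_decoding_table(make_trna_set(), include_pseudogenes = TRUE)
  for (codon in tab$codon) {
    want <- if (codon %in% names(decoding_grid_expected)) decoding_grid_expected[[codon]]
    else if (codon %in% c("UAA", "UAG", "UGA")) "stop"
    else "none"
    expect_identical(tab[tab$codon == codon, "status"], want)
  }
  # the genes printed in the decoded cells
  expect_equal(tab["UAC", "gene"], "trnY(gua)")
  expect_equal(tab["UGC", "gene"], "trnC(gca)")
  expect_equal(tab["UGG", "gene"], "trnW(cca)-cp")
  expect_equal(tab["CCA", "gene"], "trnP(ugg)")
  expect_equal(tab["CAC", "gene"], "trnH(gug)-cp")
  expect_equal(tab["AAC", "gene"], "trnN(guu)-cp")
  expect_equal(tab["AUA", "gene"], "trnI(cau)")
  expect_equal(tab["AUG", "gene"], "trnfM(cau)")
  expect_equal(tab["GAA", "gene"], "trnE(uuc)")
})

test_that("capacity summary gives 17 codons and 9 amino acids; edge cases hold", {
  tab <- build_decoding_table(make_trna_set(), include_pseudogenes = TRUE)
  cap <- capacity_summary(tab)
  expect_equal(cap$codons_decoded, 17L)
  expect_equal(cap$amino_acids_covered, 9L)
  # pseudogene exclusion cannot grow the set
  cap_np <- capacity_summary(build_decoding_table(make_trna_set(),
                                                  include_pseudogenes = FALSE))
  expect_lte(cap_np$codons_decoded, 17L)
  empty <- build_decoding_table(make_trna_set(data.frame()))
  expect_equal(capacity_summary(empty), list(codons_decoded = 0L,
                                             amino_acids_covered = 0L))
  solo <- build_decoding_table(make_trna_set(data.frame(
    name = "trnW(cca)-cp", anticodon = "CCA", amino_acid = "Trp")))
  expect_equal(solo$codon[solo$status %in% c("direct", "wobble")], "UGG")
})

test_that("a designed full set reaches all 61 sense codons, 20 amino acids", {
  # one U34 superwobble tRNA per family box; split boxes covered purine-side
  # by U34 and pyrimidine-side by G34; AUA via lysidine; AUG via initiator;
  # UGG via C34
  code <- mitodyn:::standard_code_rna()
  boxes <- unique(substr(names(code), 1L, 2L))
  genes <- list()
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  for (b in boxes) {
    aas <- stats::setNames(code[paste0(b, c("U", "C", "A", "G"))],
                           c("U", "C", "A", "G"))
    ac23 <- paste0(wc[substr(b, 2L, 2L)], wc[substr(b, 1L, 1L)])
    if (length(unique(aas)) == 1L && !any(aas == "*")) {
      genes[[length(genes) + 1L]] <- data.frame(
        name = paste0("fam_", b), anticodon = paste0("U", ac23),
        amino_acid = mitodyn:::aa_three[aas[1L]])
    } else {
      if (!aas[["U"]] == "*") genes[[length(genes) + 1L]] <- data.frame(
        name = paste0("pyr_", b), anticodon = paste0("G", ac23),
        amino_acid = mitodyn:::aa_three[aas[["U"]]])
      if (!aas[["A"]] == "*") genes[[length(genes) + 1L]] <- data.frame(
        name = paste0("purA_", b), anticodon = paste0("U", ac23),
        amino_acid = mitodyn:::aa_three[aas[["A"]]])
      if (!aas[["G"]] == "*" && aas[["G"]] != aas[["A"]])
        genes[[length(genes) + 1L]] <- data.frame(
          name = paste0("purG_", b), anticodon = paste0("C", ac23),
          amino_acid = mitodyn:::aa_three[aas[["G"]]])
    }
  }
  genes[[length(genes) + 1L]] <- data.frame(
    name = "trnI_lys", anticodon = "CAU", amino_acid = "Ile")
  full <- do.call(rbind, genes)
  full$lysidine <- full$name == "trnI_lys"
  tab <- build_decoding_table(make_trna_set(full))
  cap <- capacity_summary(tab)
  expect_equal(cap$codons_decoded, 61L)
  expect_equal(cap$amino_acids_covered, 20L)
})

test_that("decoding is monotone: adding a gene never shrinks the set", {
  base <- make_trna_set()
  decoded <- function(t) sum(t$status %in% c("direct", "wobble"))
  full <- decoded(build_decoding_table(base))
  for (drop in seq_len(nrow(base))) {
    sub <- make_trna_set(as.data.frame(base)[-drop, ])
    expect_lte(decoded(build_decoding_table(sub)), full)
  }
  # wobble codons are reachable only with wobble; direct also without
  tab <- build_decoding_table(base)
  expect_true(all(tab$status[tab$codon %in% c("UAC", "CCA", "GAA")] == "direct"))
  expect_true(all(tab$status[tab$codon %in% c("UAU", "CCG", "GAG")] == "wobble"))
})

test_that("capacity comparison reports symmetric differences", {
  t1 <- build_decoding_table(make_trna_set())
  expect_length(compare_capacity(t1, t1)$codons_gained, 0L)
  empty <- build_decoding_table(make_trna_set(data.frame()))
  cmp <- compare_capacity(empty, t1)
  expect_length(cmp$codons_gained, 17L)
  expect_length(cmp$amino_acids_gained, 9L)
  # adding one G34 gene gains exactly its two codons
  plus <- make_trna_set(rbind(as.data.frame(make_trna_set()),
    data.frame(name = "trnF(gaa)", anticodon = "GAA", amino_acid = "Phe",
               chloroplast_origin = FALSE, pseudogene = FALSE,
               initiator = FALSE, lysidine = FALSE)))
  cmp2 <- compare_capacity(t1, build_decoding_table(plus))
  expect_setequal(cmp2$codons_gained, c("UUU", "UUC"))
})
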