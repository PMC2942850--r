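#' Codon third-position bases read by an anticodon under expanded wobble rules
#'
#' The first anticodon base (position 34) pairs with the codon third position.
#' Under the expanded rules: G34 reads C (Watson-Crick) and U (GU wobble);
#' unmodified C34 reads G only; lysidine-modified C34 reads A only (and
#' switches the tRNA to isoleucine identity); U34 reads A (Watson-Crick) and
#' G (wobble), extended to all four bases ("superwobble") when the codon box
#' is four-fold degenerate (a family box); A34 reads U only.
#'
#' @param anticodon_34 the anticodon wobble base, one of A/C/G/U.
#' @param family_box is the decoded codon box four-fold degenerate?
#' @param lysidine is C34 lysidine-modified?
#' @return Data frame with columns `base` (codon third position) and `status`
#'   (`"direct"` or `"wobble"`).
#' @export
wobble_partners <- function(anticodon_34, family_box = FALSE, lysidine = FALSE) {
  b <- toupper(anticodon_34)
  if (!b %in% RNA_BASES) stop_mitodyn("anticodon_34 must be one of A, C, G, U")
  if (lysidine && b != "C")
    stop_mitodyn("lysidine modification applies only to C34")
  partners <- switch(b,
    G = data.frame(base = c("C", "U"), status = c("direct", "wobble")),
    C = if (lysidine) data.frame(base = "A", status = "direct")
        else data.frame(base = "G", status = "direct"),
    U = if (family_box)
          data.frame(base = c("A", "G", "U", "C"),
                     status = c("direct", "wobble", "wobble", "wobble"))
        else data.frame(base = c("A", "G"), status = c("direct", "wobble")),
    A = data.frame(base = "U", status = "direct"))
  partners$base <- as.character(partners$base)
  partners$status <- as.character(partners$status)
  partners
}

rna_wc <- c(A = "U", C = "G", G = "C", U = "A")

# the standard genetic code over RNA codons
standard_code_rna <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("T", "U", names(code))
  code
}

# four-fold degenerate codon box (same amino acid for all 4 third bases)?
is_family_box <- function(codon12, code) {
  aas <- code[paste0(codon12, RNA_BASES)]
  !any(aas == "*") && length(unique(aas)) == 1L
}

#' Build the codon decoding table for a tRNA gene set
#'
#' Closes the gene set under the expanded wobble rules
#' ([wobble_partners()]): each sense codon is `direct` if some gene's
#' anticodon Watson-Crick-matches it at all three positions (with the
#' position-34 rules for the third), `wobble` if it is reachable only through
#' a wobble partner, else `none`.  A gene only decodes codons whose
#' translation matches its amino-acid identity (lysidine-C34 genes read AUA as
#' isoleucine); the initiator tRNA decodes AUG only; stop codons are never
#' decoded.  Pseudogenes are included only when `include_pseudogenes = TRUE`.
#'
#' @param trnas a `trna_set` (see [make_trna_set()]).
#' @param include_pseudogenes include genes flagged as potential pseudogenes.
#' @param code named character vector mapping RNA codons to one-letter amino
#'   acids (`"*"` = stop); default the standard genetic code, which plant
#'   mitochondria use.
#' @return A `decoding_table`: data frame with one row per codon (`codon`,
#'   `amino_acid` three-letter, `status` in direct/wobble/none/stop, `gene`).
#' @export
build_decoding_table <- function(trnas, include_pseudogenes = TRUE,
                                 code = standard_code_rna()) {
  trnas <- make_trna_set(trnas)
  if (anyDuplicated(trnas$name))
    warning("duplicate tRNA gene names in the set", call. = FALSE)
  if (!include_pseudogenes) trnas <- trnas[!trnas$pseudogene, , drop = FALSE]

  codons <- names(code)
  tab <- data.frame(codon = codons,
                    amino_acid = aa_three[code],
                    status = ifelse(code == "*", "stop", "none"),
                    gene = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(tab) <- codons

  for (g in seq_len(nrow(trnas))) {
    ac <- trnas$anticodon[g]
    a34 <- substr(ac, 1L, 1L)
    codon12 <- paste0(rna_wc[substr(ac, 3L, 3L)], rna_wc[substr(ac, 2L, 2L)])
    fam <- is_family_box(codon12, code)
    identity <- if (trnas$lysidine[g]) "Ile" else trnas$amino_acid[g]
    partners <- wobble_partners(a34, family_box = fam,
                                lysidine = trnas$lysidine[g])
    for (r in seq_len(nrow(partners))) {
      codon <- paste0(codon12, partners$base[r])
      if (code[[codon]] == "*") next
      if (aa_three[code[[codon]]] != identity) next
      if (trnas$initiator[g] && codon != "AUG") next
      new_status <- partners$status[r]
      cur <- tab[codon, "status"]
      better <- cur == "none" || (cur == "wobble" && new_status == "direct")
      if (better) {
        tab[codon, "status"] <- new_status
        tab[codon, "gene"] <- trnas$name[g]
      }
    }
  }
  structure(tab, class = c("decoding_table", "data.frame"),
            code = code, include_pseudogenes = include_pseudogenes)
}

# one-letter -> three-letter amino acid codes (stop = "*")
aa_three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "*")

#' Summarise decoding capacity
#'
#' @param table a `decoding_table`.
#' @return List with `codons_decoded` (of the 61 sense codons) and
#'   `amino_acids_covered` (of the 20; initiator methionine counts as Met).
#' @export
capacity_summary <- function(table) {
  stopifnot(inherits(table, "decoding_table"))
  decoded <- table$status %in% c("direct", "wobble")
  list(codons_decoded = sum(decoded),
       amino_acids_covered = length(unique(table$amino_acid[decoded])))
}

#' Compare the decoding capacity of two tRNA sets
#'
#' @param table_a,table_b `decoding_table` objects built on the same genetic
#'   code.
#' @return List of class `capacity_comparison`: codons/amino acids gained and
#'   lost going from `table_a` to `table_b`.
#' @export
compare_capacity <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "decoding_table"), inherits(table_b, "decoding_table"))
  if (!identical(attr(table_a, "code"), attr(table_b, "code")))
    stop_mitodyn("decoding tables use different genetic codes")
  dec <- function(t) t$codon[t$status %in% c("direct", "wobble")]
  aas <- function(t) unique(t$amino_acid[t$status %in% c("direct", "wobble")])
  structure(list(
    codons_gained = setdiff(dec(table_b), dec(table_a)),
    codons_lost = setdiff(dec(table_a), dec(table_b)),
    amino_acids_gained = setdiff(aas(table_b), aas(table_a)),
    amino_acids_lost = setdiff(aas(table_a), aas(table_b))
  ), class = "capacity_comparison")
}

#' @export
print.capacity_comparison <- function(x, ...) {
  cat(sprintf("<capacity_comparison> +%d/-%d codons, +%d/-%d amino acids\n",
              length(x$codons_gained), length(x$codons_lost),
              length(x$amino_acids_gained), length(x$amino_acids_lost)))
  invisible(x)
}

#' @export
print.decoding_table <- function(x, ...) {
  if (nrow(x) != 64L) {        # a subset: plain data frame display
    print(as.data.frame(x))
    return(invisible(x))
  }
  cap <- capacity_summary(x)
  cat(sprintf("<decoding_table> %d of 61 sense codons decoded, %d of 20 amino acids\n\n",
              cap$codons_decoded, cap$amino_acids_covered))
  # 16 x 4 grid in the classic codon-table layout
  b1 <- RNA_BASES[c(4L, 2L, 1L, 3L)]  # U C A G
  for (p1 in b1) for (p3 in b1) {
    row <- character(0)
    for (p2 in b1) {
      codon <- paste0(p1, p2, p3)
      r <- x[x$codon == codon, ]
      lab <- if (r$status == "stop") "*"
      else if (r$status == "none") "--"
      else if (r$status == "wobble") "wobble"
      else r$gene
      row <- c(row, sprintf("%s %-4s %-14s", codon, r$amino_acid, lab))
    }
    cat(paste(row, collapse = " "), "\n")
  }
  invisible(x)
}
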