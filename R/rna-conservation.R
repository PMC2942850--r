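#' Classify substitutions against a reference secondary structure
#'
#' Each position where `alt_seq` differs from `ref_seq` is classified:
#' `loop` (unpaired position), `helix_compensatory` (both partners of a pair
#' substituted and the resulting pair is still Watson-Crick or GU — e.g. a
#' C:G to G:C change), `helix_conservative` (partner unchanged but the new
#' pair is still valid — e.g. A:U to G:U), or `helix_disruptive` (anything
#' else in a helix).  The categories are exhaustive and mutually exclusive.
#'
#' @param ref_seq,alt_seq equal-length RNA sequences.
#' @param structure a `secondary_structure` (valid for `ref_seq`) or
#'   dot-bracket string.
#' @return A `substitution_report`: `substitutions` (position, ref, alt,
#'   category) and `counts` per category.
#' @export
classify_substitutions <- function(ref_seq, alt_seq, structure) {
  st <- if (inherits(structure, "secondary_structure")) structure
  else parse_structure(structure)
  ref <- strsplit(toupper(gsub("T", "U", ref_seq)), "")[[1L]]
  alt <- strsplit(toupper(gsub("T", "U", alt_seq)), "")[[1L]]
  if (length(ref) != length(alt))
    stop_mitodyn("ref_seq and alt_seq must have equal length")
  if (length(ref) != st$length)
    stop_mitodyn("sequence length does not match the structure")
  partner <- integer(st$length)
  if (nrow(st$pairs)) {
    partner[st$pairs[, 1L]] <- st$pairs[, 2L]
    partner[st$pairs[, 2L]] <- st$pairs[, 1L]
  }
  diffs <- which(ref != alt)
  category <- character(length(diffs))
  for (k in seq_along(diffs)) {
    p <- diffs[k]
    q <- partner[p]
    if (q == 0L) { category[k] <- "loop"; next }
    i <- min(p, q); j <- max(p, q)
    valid <- !is.na(pair_type_index(alt[i], alt[j]))
    partner_sub <- q %in% diffs
    category[k] <-
      if (partner_sub && valid) "helix_compensatory"
      else if (!partner_sub && valid) "helix_conservative"
      else "helix_disruptive"
  }
  levels <- c("loop", "helix_conservative", "helix_compensatory", "helix_disruptive")
  structure(list(
    substitutions = data.frame(position = diffs, ref = ref[diffs],
                               alt = alt[diffs], category = category,
                               stringsAsFactors = FALSE),
    counts = table(factor(category, levels = levels))
  ), class = "substitution_report")
}

#' @export
print.substitution_report <- function(x, ...) {
  cat(sprintf("<substitution_report> %d substitution(s): %s\n",
              nrow(x$substitutions),
              paste(names(x$counts), as.integer(x$counts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Permutation test for secondary-structure conservation
#'
#' Tests whether an observed diverged sequence preserves a conserved
#' secondary structure better than expected by chance, given its substitution
#' count.  With k = Hamming(ref, observed), `N` null sequences are generated
#' by randomly placing exactly k substitutions into the reference
#' ([mutate_k()]); every sequence is scored on the *fixed* reference
#' structure (lenient mode, so disrupted pairs simply lose their stacking
#' terms), and the empirical p-value is
#' `(1 + #\{null dG <= observed dG\}) / (N + 1)` — small when the observed
#' sequence is among the most stable, never exactly 0.
#'
#' @param ref_seq the conserved reference sequence.
#' @param structure its secondary structure (dot-bracket or parsed).
#' @param observed_seq the diverged sequence under test (same length,
#'   Hamming distance >= 1).
#' @param N number of null replicates (the classic choice is 10,000).
#' @param seed integer seed.
#' @param params energy parameters.
#' @param lenient_stack stacking score for invalidated pairs.
#' @return A `conservation_test` object: `observed_dg`, `null_dg` (length N),
#'   `p.value`, `k`, `N`, `seed`.
#' @export
conservation_test <- function(ref_seq, structure, observed_seq, N = 1000L,
                              seed = 1L, params = default_energy_params(),
                              lenient_stack = 0) {
  st <- if (inherits(structure, "secondary_structure")) structure
  else parse_structure(structure)
  ref <- toupper(gsub("T", "U", ref_seq))
  obs <- toupper(gsub("T", "U", observed_seq))
  if (nchar(ref) != nchar(obs))
    stop_mitodyn("observed_seq must have the same length as ref_seq")
  refv <- match(strsplit(ref, "")[[1L]], RNA_BASES)
  obsv <- match(strsplit(obs, "")[[1L]], RNA_BASES)
  k <- sum(refv != obsv)
  if (k < 1L)
    stop_mitodyn("observed sequence is identical to the reference; no test possible")
  N <- as.integer(N)
  dec <- structure_decomposition(st)
  n <- length(refv)
  null_mat <- with_seed(seed, {
    m <- matrix(refv, nrow = n, ncol = N)
    for (b in seq_len(N)) {
      pos <- sample.int(n, k)
      shift <- sample.int(3L, k, replace = TRUE)
      m[pos, b] <- (m[pos, b] - 1L + shift) %% 4L + 1L
    }
    m
  })
  null_dg <- energies_on_structure(null_mat, dec, params, lenient_stack)
  observed_dg <- energies_on_structure(matrix(obsv, ncol = 1L), dec, params,
                                       lenient_stack)
  p <- (1 + sum(null_dg <= observed_dg)) / (N + 1)
  structure(list(observed_dg = observed_dg, null_dg = null_dg,
                 p.value = p, k = k, N = N, seed = seed),
            class = "conservation_test")
}

#' @export
print.conservation_test <- function(x, ...) {
  q <- stats::quantile(x$null_dg, c(0.05, 0.5, 0.95))
  cat(sprintf(
    "Structure conservation permutation test\n  k = %d substitutions, N = %d replicates\n  observed dG = %.2f kcal/mol; null 5%%/50%%/95%% = %.2f / %.2f / %.2f\n  empirical p = %.4g\n",
    x$k, x$N, x$observed_dg, q[1L], q[2L], q[3L], x$p.value))
  invisible(x)
}

#' A compact 5S-rRNA-like secondary structure
#'
#' A 118-nt five-helix layout (one closing helix plus two helical arms, each
#' interrupted by an internal loop) used as the default substrate for
#' structure-conservation simulations.  It mimics the overall architecture of
#' plant 5S rRNA — ~35 base pairs in five helices around a central multiloop
#' — without copying any real sequence.
#'
#' @return The dot-bracket string (length 118, 35 pairs).
#' @export
example_5s_structure <- function() {
  paste0(
    "..",
    strrep("(", 9L), "....",
    strrep("(", 7L), "..",
    strrep("(", 8L), strrep(".", 14L), strrep(")", 8L),
    "...", strrep(")", 7L), "..",
    strrep("(", 6L), "..", strrep("(", 5L), strrep(".", 12L),
    strrep(")", 5L), ".", strrep(")", 6L),
    "...", strrep(")", 9L), "...")
}
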