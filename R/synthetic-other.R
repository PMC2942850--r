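#' Build a tRNA gene set
#'
#' Either returns a named preset or validates a user-supplied gene table.  The
#' preset `"silene_latifolia_table1"` encodes the 11 mitochondrially encoded
#' tRNA genes of *Silene latifolia*: six native genes — trnY(gua), trnC(gca),
#' trnP(ugg), trnE(uuc), trnI(cau) (lysidine-modified C34, isoleucine
#' identity) and the initiator trnfM(cau) — plus five genes of chloroplast
#' origin — trnW(cca)-cp, trnH(gug)-cp, trnN(guu)-cp and the two potential
#' pseudogenes trnP-cp and trnM-cp(cau).
#'
#' @param preset_or_spec a preset name, or a data frame with columns `name`,
#'   `anticodon` (3-mer, 5'->3', RNA alphabet), `amino_acid` (three-letter
#'   code), and optional logical columns `chloroplast_origin`, `pseudogene`,
#'   `initiator`, `lysidine`.  An empty data frame gives an empty gene set.
#' @return A data frame of class `trna_set`.
#' @export
make_trna_set <- function(preset_or_spec = "silene_latifolia_table1") {
  if (is.character(preset_or_spec)) {
    if (preset_or_spec != "silene_latifolia_table1")
      stop_mitodyn("unknown tRNA preset: ", preset_or_spec)
    path <- system.file("extdata", "silene_latifolia_table1.tsv",
                        package = "mitodyn", mustWork = TRUE)
    return(read_trna_tsv(path))
  }
  spec <- as.data.frame(preset_or_spec, stringsAsFactors = FALSE)
  if (nrow(spec) == 0L) {
    spec <- data.frame(name = character(0), anticodon = character(0),
                       amino_acid = character(0),
                       chloroplast_origin = logical(0), pseudogene = logical(0),
                       initiator = logical(0), lysidine = logical(0))
    class(spec) <- c("trna_set", "data.frame")
    return(spec)
  }
  req <- c("name", "anticodon", "amino_acid")
  if (!all(req %in% names(spec)))
    stop_mitodyn("tRNA spec needs columns: ", paste(req, collapse = ", "))
  for (fl in c("chloroplast_origin", "pseudogene", "initiator", "lysidine"))
    if (is.null(spec[[fl]])) spec[[fl]] <- FALSE
  spec$anticodon <- toupper(gsub("T", "U", toupper(spec$anticodon)))
  if (any(nchar(spec$anticodon) != 3L) ||
      any(!strsplit(paste(spec$anticodon, collapse = ""), "")[[1]] %in% RNA_BASES))
    stop_mitodyn("anticodons must be 3-mers over A/C/G/U")
  bad_lys <- spec$lysidine & substr(spec$anticodon, 1L, 1L) != "C"
  if (any(bad_lys))
    stop_mitodyn("lysidine modification requires C at anticodon position 34")
  spec <- spec[, c(req, "chloroplast_origin", "pseudogene", "initiator", "lysidine")]
  class(spec) <- c("trna_set", "data.frame")
  spec
}

#' Generate a random RNA sequence compatible with a fixed secondary structure
#'
#' Every base pair of the dot-bracket structure is filled with a pair type
#' drawn uniformly from the six Watson-Crick and GU wobble pairs; unpaired
#' positions are uniform over A/C/G/U.
#'
#' @param length sequence length; must match the structure.
#' @param structure dot-bracket string, or a parsed [parse_structure()] object.
#' @param seed integer seed.
#' @return An RNA sequence string.
#' @export
make_structured_rna <- function(length, structure, seed = 1L) {
  st <- if (inherits(structure, "secondary_structure")) structure
  else parse_structure(structure)
  if (st$length != length)
    stop_mitodyn("length (", length, ") does not match structure length (",
                 st$length, ")")
  pair_types <- c("AU", "UA", "CG", "GC", "GU", "UG")
  with_seed(seed, {
    s <- sample(RNA_BASES, length, replace = TRUE)
    if (nrow(st$pairs)) {
      pt <- pair_types[sample.int(6L, nrow(st$pairs), replace = TRUE)]
      s[st$pairs[, 1L]] <- substr(pt, 1L, 1L)
      s[st$pairs[, 2L]] <- substr(pt, 2L, 2L)
    }
    paste(s, collapse = "")
  })
}

#' Place exactly k random substitutions in a sequence
#'
#' `k` distinct positions are chosen uniformly without replacement and each is
#' substituted by a uniformly chosen *different* base, so the Hamming distance
#' between input and output is exactly `k`.  The alphabet (DNA or RNA) is
#' inferred from the input.
#'
#' @param sequence a nucleotide string.
#' @param k number of substitutions, `0 <= k <= nchar(sequence)`.
#' @param seed integer seed (`NULL` uses the ambient RNG stream).
#' @return The mutated sequence string.
#' @export
mutate_k <- function(sequence, k, seed = NULL) {
  n <- nchar(sequence)
  k <- as.integer(k)
  if (k < 0L || k > n)
    stop_mitodyn("k must be between 0 and the sequence length (", n, ")")
  if (k == 0L) return(sequence)
  alphabet <- if (grepl("U", sequence, fixed = TRUE)) RNA_BASES else DNA_BASES
  with_seed(seed, {
    v <- strsplit(sequence, "")[[1]]
    pos <- sample.int(n, k)
    v[pos] <- mutate_bases(v[pos], alphabet)
    paste(v, collapse = "")
  })
}

# substitute each base by a uniformly chosen different base
mutate_bases <- function(bases, alphabet) {
  idx <- match(bases, alphabet)
  shift <- sample.int(length(alphabet) - 1L, length(bases), replace = TRUE)
  alphabet[(idx - 1L + shift) %% length(alphabet) + 1L]
}

#' Generate a three-sequence alignment with a planted gene-conversion tract
#'
#' Builds an ancestral sequence, a donor diverged from it at
#' `donor_divergence`, an outgroup diverged at `outgroup_divergence`, and a
#' recipient equal to the ancestral sequence except inside the tract, where it
#' carries the donor sequence (a clean conversion event).  Inside the tract
#' the recipient-donor identity is 1; outside it is about
#' `1 - donor_divergence`.
#'
#' @param recipient_len alignment length in columns (no indels are simulated).
#' @param donor_divergence per-site substitution probability of the donor
#'   relative to the ancestor, in (0, 1).
#' @param tract c(start, length) of the converted tract in 0-based columns.
#' @param outgroup_divergence per-site substitution probability of the
#'   outgroup relative to the ancestor.
#' @param seed integer seed.
#' @return A list of class `conversion_alignment`: `sequences` (named
#'   character vector: recipient, donor, outgroup) and `tract` (the planted
#'   0-based half-open column interval).
#' @export
make_conversion_alignment <- function(recipient_len, donor_divergence = 0.25,
                                      tract = c(0L, 0L),
                                      outgroup_divergence = 0.02, seed = 1L) {
  recipient_len <- as.integer(recipient_len)
  tract <- as.integer(tract)
  if (tract[2L] < 0L || tract[1L] < 0L ||
      tract[1L] + tract[2L] > recipient_len)
    stop_mitodyn("tract must lie within the sequence")
  for (d in c(donor_divergence, outgroup_divergence))
    if (d < 0 || d >= 1) stop_mitodyn("divergences must be in [0, 1)")
  with_seed(seed, {
    anc <- strsplit(random_dna(recipient_len), "")[[1]]
    donor <- anc
    hit <- which(stats::runif(recipient_len) < donor_divergence)
    donor[hit] <- mutate_bases(donor[hit], DNA_BASES)
    outg <- anc
    hit <- which(stats::runif(recipient_len) < outgroup_divergence)
    outg[hit] <- mutate_bases(outg[hit], DNA_BASES)
    recip <- anc
    if (tract[2L] > 0L) {
      cols <- (tract[1L] + 1L):(tract[1L] + tract[2L])
      recip[cols] <- donor[cols]
    }
    structure(list(
      sequences = c(recipient = paste(recip, collapse = ""),
                    donor = paste(donor, collapse = ""),
                    outgroup = paste(outg, collapse = "")),
      tract = c(start = tract[1L], end = tract[1L] + tract[2L])
    ), class = "conversion_alignment")
  })
}

#' @export
print.conversion_alignment <- function(x, ...) {
  cat(sprintf("<conversion_alignment> %d columns, tract [%d, %d)\n",
              nchar(x$sequences[[1L]]), x$tract[["start"]], x$tract[["end"]]))
  invisible(x)
}
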