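#' Parse a dot-bracket secondary structure
#'
#' Single bracket family (no pseudoknots).  Pairs are recovered by stack
#' matching; the object round-trips back to the input string.
#'
#' @param dotbracket a string over `.`, `(` and `)`.
#' @return A `secondary_structure`: `dotbracket`, `pairs` (two-column matrix
#'   of 1-based positions, i < j), `length`.
#' @export
parse_structure <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1L]]
  if (any(!chars %in% c(".", "(", ")")))
    stop_mitodyn("structure may contain only '.', '(' and ')'")
  stack <- integer(0L)
  pairs <- matrix(integer(0L), ncol = 2L)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop_mitodyn("unbalanced structure: unmatched ')' at position ", i)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop_mitodyn("unbalanced structure: unmatched '(' at position ", stack[1L])
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(dotbracket = dotbracket, pairs = pairs,
                 length = length(chars)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d base pairs\n%s\n",
              x$length, nrow(x$pairs), x$dotbracket))
  invisible(x)
}

#' @export
as.character.secondary_structure <- function(x, ...) x$dotbracket

PAIR_TYPES <- c("AU", "CG", "GC", "GU", "UA", "UG")

#' Load nearest-neighbor energy parameters
#'
#' Reads the editable TSV parameter format: stacking free energies for all
#' Watson-Crick and GU pair adjacencies, size-dependent hairpin/bulge/internal
#' loop penalties (extrapolated logarithmically beyond the tabulated sizes),
#' and affine multiloop terms.  The shipped default is a reduced Turner-style
#' 37 degrees-C set in kcal/mol: loop penalties depend on loop size only (no
#' sequence-dependent mismatch terms, dangles, or terminal-AU penalties), and
#' stacking energies are averaged over pair orientation, so the energy of a
#' structure depends only on the *composition* of each base pair (A:U, C:G or
#' G:U).  Under this reduction a compensatory substitution pair that flips a
#' pair's orientation (e.g. C:G to G:C) leaves the free energy exactly
#' unchanged — the property the structure-conservation test treats as the
#' signature of compensated change.
#'
#' @param path TSV file with columns `term`, `key1`, `key2`, `dg`; default the
#'   packaged parameter set.
#' @return An `energy_params` object.
#' @export
read_energy_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nn_energy_params.tsv",
                        package = "mitodyn", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  stk <- raw[raw$term == "stack", ]
  stack <- matrix(NA_real_, 6L, 6L, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(match(stk$key1, PAIR_TYPES), match(stk$key2, PAIR_TYPES))] <- stk$dg
  if (anyNA(stack))
    stop_mitodyn("stack table does not cover all pair adjacencies")
  loop_tab <- function(type) {
    d <- raw[raw$term == type, ]
    v <- d$dg[order(as.integer(d$key1))]
    names(v) <- sort(as.integer(d$key1))
    v
  }
  ml <- raw[raw$term == "multiloop", ]
  mlv <- stats::setNames(ml$dg, ml$key1)
  lxc <- raw$dg[raw$term == "extrapolation" & raw$key1 == "lxc"]
  hp <- loop_tab("hairpin"); bu <- loop_tab("bulge"); int <- loop_tab("internal")
  if (any(c(hp, bu, int) < 0)) stop_mitodyn("loop penalties must be >= 0")
  structure(list(stack = stack, hairpin = hp, bulge = bu, internal = int,
                 multiloop = mlv, lxc = lxc), class = "energy_params")
}

#' @rdname read_energy_params
#' @export
default_energy_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_energy_params()
    cache
  }
})

loop_penalty <- function(table, size, lxc) {
  sizes <- as.integer(names(table))
  if (size < min(sizes))
    stop_mitodyn("loop of size ", size, " below the tabulated minimum (",
                 min(sizes), ")")
  if (size <= max(sizes)) return(unname(table[as.character(size)]))
  unname(table[as.character(max(sizes))]) + lxc * log(size / max(sizes))
}

pair_type_index <- function(b5, b3) {
  match(paste0(b5, b3), PAIR_TYPES)      # NA for non-WC/GU
}

# Unique loop decomposition of a pseudoknot-free structure.
# Returns stacks (pairs of adjacent base pairs) and loops (type + size).
structure_decomposition <- function(structure) {
  pairs <- structure$pairs
  n <- structure$length
  pt <- integer(n)
  if (nrow(pairs)) {
    pt[pairs[, 1L]] <- pairs[, 2L]
    pt[pairs[, 2L]] <- pairs[, 1L]
  }
  stacks <- matrix(integer(0L), ncol = 4L)   # i, j, i+1, j-1
  loops <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- unname(pairs[r, 1L]); j <- unname(pairs[r, 2L])
    # children: maximal pairs directly enclosed by (i, j)
    kids <- matrix(integer(0L), ncol = 2L)
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) { kids <- rbind(kids, c(k, pt[k])); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    if (nrow(kids) == 1L && kids[1L, 1L] == i + 1L && kids[1L, 2L] == j - 1L) {
      stacks <- rbind(stacks, c(i, j, i + 1L, j - 1L))
    } else if (nrow(kids) == 0L) {
      loops[[length(loops) + 1L]] <- list(type = "hairpin", size = j - i - 1L)
    } else if (nrow(kids) == 1L) {
      l <- kids[1L, 1L] - i - 1L
      rr <- j - kids[1L, 2L] - 1L
      loops[[length(loops) + 1L]] <-
        list(type = if (l == 0L || rr == 0L) "bulge" else "internal",
             size = l + rr)
    } else {
      unpaired <- (j - i - 1L) - sum(kids[, 2L] - kids[, 1L] + 1L)
      loops[[length(loops) + 1L]] <-
        list(type = "multiloop", branches = nrow(kids) + 1L, size = unpaired)
    }
  }
  list(stacks = stacks, loops = loops, pairs = pairs)
}

loop_terms_total <- function(loops, params) {
  total <- 0
  for (lp in loops) {
    total <- total + switch(lp$type,
      hairpin = loop_penalty(params$hairpin, lp$size, params$lxc),
      bulge = loop_penalty(params$bulge, lp$size, params$lxc),
      internal = loop_penalty(params$internal, lp$size, params$lxc),
      multiloop = params$multiloop[["offset"]] +
        params$multiloop[["branch"]] * lp$branches +
        params$multiloop[["unpaired"]] * lp$size)
  }
  unname(total)
}

#' Free energy of a sequence folded into a fixed secondary structure
#'
#' Sums the structure's unique loop decomposition: stacking terms over
#' adjacent base pairs in helices, size-dependent hairpin/bulge/internal loop
#' penalties, affine multiloop terms; the exterior loop contributes 0.  This
#' is fixed-structure *evaluation*, not folding: the structure is given, and
#' the question is how well the sequence supports it.
#'
#' By default every paired position must form a Watson-Crick or GU pair.  In
#' lenient mode (used to score mutant sequences against a conserved
#' reference structure) invalid pairs are allowed: any stacking term
#' involving an invalid pair contributes `lenient_stack` (default 0, i.e. the
#' favourable stacking is simply lost).
#'
#' @param sequence RNA sequence (a DNA string is converted).
#' @param structure a `secondary_structure` or dot-bracket string.
#' @param params an `energy_params` set (default [default_energy_params()]).
#' @param lenient allow non-WC/GU pairs (scored via `lenient_stack`).
#' @param lenient_stack energy (kcal/mol) assigned to a stacking term whose
#'   pairs are not both valid.
#' @return Free energy in kcal/mol.
#' @export
evaluate_energy <- function(sequence, structure, params = default_energy_params(),
                            lenient = FALSE, lenient_stack = 0) {
  st <- if (inherits(structure, "secondary_structure")) structure
  else parse_structure(structure)
  seq <- toupper(gsub("T", "U", sequence))
  if (nchar(seq) != st$length)
    stop_mitodyn("sequence length (", nchar(seq),
                 ") does not match structure length (", st$length, ")")
  v <- strsplit(seq, "")[[1L]]
  if (nrow(st$pairs)) {
    ptype <- pair_type_index(v[st$pairs[, 1L]], v[st$pairs[, 2L]])
    if (!lenient && anyNA(ptype)) {
      bad <- which(is.na(ptype))[1L]
      stop_mitodyn("position pair (", st$pairs[bad, 1L], ", ",
                   st$pairs[bad, 2L], ") is ", v[st$pairs[bad, 1L]], ":",
                   v[st$pairs[bad, 2L]],
                   ", not a Watson-Crick or GU pair (use lenient = TRUE to score)")
    }
  }
  dec <- structure_decomposition(st)
  total <- loop_terms_total(dec$loops, params)
  if (nrow(dec$stacks)) {
    p1 <- pair_type_index(v[dec$stacks[, 1L]], v[dec$stacks[, 2L]])
    p2 <- pair_type_index(v[dec$stacks[, 3L]], v[dec$stacks[, 4L]])
    term <- ifelse(is.na(p1) | is.na(p2), lenient_stack,
                   params$stack[cbind(p1, p2)])
    total <- total + sum(term)
  }
  unname(total)
}

# Vectorised energies of many same-length sequences on one fixed structure
# (lenient mode).  `mat` is an integer matrix (positions x sequences) with
# bases coded 1..4 = A, C, G, U.
energies_on_structure <- function(mat, dec, params, lenient_stack = 0) {
  const <- loop_terms_total(dec$loops, params)
  nseq <- ncol(mat)
  total <- rep(const, nseq)
  if (nrow(dec$stacks) == 0L) return(total)
  # pair-type code: 4*(b5-1) + b3 -> index into PAIR_TYPES (NA if invalid)
  code2type <- rep(NA_integer_, 16L)
  for (t in seq_along(PAIR_TYPES)) {
    b5 <- match(substr(PAIR_TYPES[t], 1L, 1L), RNA_BASES)
    b3 <- match(substr(PAIR_TYPES[t], 2L, 2L), RNA_BASES)
    code2type[4L * (b5 - 1L) + b3] <- t
  }
  S <- matrix(lenient_stack, 7L, 7L)
  S[1:6, 1:6] <- params$stack
  for (r in seq_len(nrow(dec$stacks))) {
    t1 <- code2type[4L * (mat[dec$stacks[r, 1L], ] - 1L) + mat[dec$stacks[r, 2L], ]]
    t2 <- code2type[4L * (mat[dec$stacks[r, 3L], ] - 1L) + mat[dec$stacks[r, 4L], ]]
    t1[is.na(t1)] <- 7L; t2[is.na(t2)] <- 7L
    total <- total + S[cbind(t1, t2)]
  }
  total
}
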