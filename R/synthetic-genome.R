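#' Specify a synthetic circular genome with a planted direct-repeat family
#'
#' Describes a circular genome carrying one identical n-copy direct repeat
#' ("core"), per-copy flanking repeat extensions shared by subsets of copies,
#' distinct single-copy regions, and optional planted restriction enzyme sites
#' at known offsets.  [make_genome()] realises the spec into sequence plus
#' ground truth.
#'
#' Layout (0-based, circular): the genome is the concatenation, for copy
#' `c = 1..n`, of `core`, then the single-copy region ("gap") between copy `c`
#' and copy `c + 1`.  Gap `c` starts with copy `c`'s right extension, ends with
#' copy `c + 1`'s left extension, and has a unique middle.  Extensions on one
#' side are nested prefixes (right side) or suffixes (left side) of a single
#' master extension sequence, so that two copies with planted lengths `l_i` and
#' `l_j` share exactly `min(l_i, l_j)` flanking bases.  At least one copy per
#' side must have extension length 0 (an extension shared by all copies would
#' be part of the core by maximality).
#'
#' Guard bases: the base immediately beyond each planted extension is forced to
#' differ from the continuation of the master extension (and pairwise between
#' copies of equal extension length), so the shared-flank lengths of the
#' emitted genome equal the planted lengths exactly.  This needs at most 4
#' distinct bases per equal-length group; infeasible specs are rejected.  When
#' a side carries no extensions at all and `n > 4`, pairwise-distinct guard
#' bases are impossible and chance shared prefixes of a few bases may occur.
#'
#' @param n_repeats number of identical direct repeat copies (>= 1).
#' @param core_length length of the repeat core in nt.
#' @param extension_left,extension_right per-copy planted extension lengths in
#'   nt (vectors of length `n_repeats`); left extensions flank the 5' side of
#'   each core copy, right extensions the 3' side.
#' @param singlecopy_lengths length of each single-copy region (the full gap
#'   between consecutive core copies, extensions included).
#' @param gc_content GC fraction of the random sequence.
#' @param enzyme_site recognition sequence planted and screened (default
#'   EcoRI, `"GAATTC"`); `NULL` disables site planting and scrubbing.
#' @param site_offsets per-gap distance (nt) of the planted site start from the
#'   repeat junction (the 3' end of the preceding core copy); `NULL` plants no
#'   sites.  Offsets must place each site in the unique part of its gap.
#' @param repeat_floor screening floor: the generator guarantees no exact
#'   repeat of at least this length other than the planted family.
#' @param seed integer seed; the generator is a pure function of (spec, seed).
#' @return An object of class `genome_spec`.
#' @seealso [make_genome()]
#' @export
genome_spec <- function(n_repeats = 6L,
                        core_length = 1362L,
                        extension_left = NULL,
                        extension_right = NULL,
                        singlecopy_lengths = NULL,
                        gc_content = 0.43,
                        enzyme_site = "GAATTC",
                        site_offsets = NULL,
                        repeat_floor = 50L,
                        seed = 1L) {
  n <- as.integer(n_repeats)
  if (is.na(n) || n < 1L) stop_mitodyn("n_repeats must be >= 1")
  core_length <- as.integer(core_length)
  if (is.null(singlecopy_lengths)) singlecopy_lengths <- rep(5400L, n)
  singlecopy_lengths <- as.integer(singlecopy_lengths)
  if (length(singlecopy_lengths) != n)
    stop_mitodyn("singlecopy_lengths must have exactly n_repeats entries")
  if (is.null(extension_left))
    extension_left <- default_extensions(n, c(0L, 12L, 60L, 150L, 250L, 400L),
                                         singlecopy_lengths)
  if (is.null(extension_right))
    extension_right <- default_extensions(n, c(0L, 20L, 80L, 180L, 300L, 450L),
                                          singlecopy_lengths)
  extension_left <- as.integer(extension_left)
  extension_right <- as.integer(extension_right)
  if (length(extension_left) != n || length(extension_right) != n)
    stop_mitodyn("extension lengths must be per-copy vectors of length n_repeats")
  if (any(extension_left < 0L) || any(extension_right < 0L))
    stop_mitodyn("extension lengths must be non-negative")
  if (n >= 2L && all(extension_left > 0L))
    stop_mitodyn("infeasible spec: all copies share a left extension; ",
                 "it would be absorbed into the core (set at least one to 0)")
  if (n >= 2L && all(extension_right > 0L))
    stop_mitodyn("infeasible spec: all copies share a right extension; ",
                 "it would be absorbed into the core (set at least one to 0)")
  # gap c holds right ext of copy c and left ext of copy c+1 (cyclic)
  nxt <- c(seq_len(n)[-1L], 1L)
  unique_len <- singlecopy_lengths - extension_right - extension_left[nxt]
  if (any(unique_len < 20L))
    stop_mitodyn("infeasible spec: extensions leave < 20 nt of unique sequence ",
                 "in a single-copy region")
  check_guard_feasible(extension_left, "left")
  check_guard_feasible(extension_right, "right")
  if (!is.null(enzyme_site)) {
    enzyme_site <- toupper(enzyme_site)
    if (nchar(enzyme_site) < 4L) stop_mitodyn("enzyme site must be >= 4 nt")
    if (is.null(site_offsets)) {
      # default: one distinctly placed site per single-copy region, clear of
      # extensions and guard bases, and inside the window where a site serves
      # both flank roles of default-span junction molecules
      sl <- nchar(enzyme_site)
      span <- min(min(singlecopy_lengths) - 100L, 2750L)
      lo <- max(max(extension_right) + 100L,
                max(singlecopy_lengths) - span + 1L)
      hi <- min(min(singlecopy_lengths - extension_left[nxt]) - sl - 10L,
                span - sl - 10L)
      if (hi - lo >= 2L * n)
        site_offsets <- lo + round(seq(0L, hi - lo, length.out = n))
    }
  }
  if (!is.null(site_offsets)) {
    if (is.null(enzyme_site)) stop_mitodyn("site_offsets given without enzyme_site")
    site_offsets <- as.integer(site_offsets)
    if (length(site_offsets) != n)
      stop_mitodyn("site_offsets must have one entry per single-copy region")
    sl <- nchar(enzyme_site)
    bad <- site_offsets < extension_right + 1L |
      site_offsets + sl > singlecopy_lengths - extension_left[nxt] - 1L
    if (any(bad))
      stop_mitodyn("infeasible spec: planted enzyme site collides with a repeat ",
                   "extension or guard base in single-copy region(s) ",
                   paste(which(bad), collapse = ", "))
    if (anyDuplicated(site_offsets))
      warning("site offsets are not pairwise distinct; virtual Southern bands may collide")
  }
  structure(list(
    n_repeats = n, core_length = core_length,
    extension_left = extension_left, extension_right = extension_right,
    singlecopy_lengths = singlecopy_lengths, gc_content = gc_content,
    enzyme_site = enzyme_site, site_offsets = site_offsets,
    repeat_floor = as.integer(repeat_floor), seed = as.integer(seed)
  ), class = "genome_spec")
}

default_extensions <- function(n, base, singlecopy) {
  if (n <= length(base)) ext <- base[seq_len(n)]
  else ext <- c(base, max(base) + seq_len(n - length(base)) * 300L)
  # keep extensions comfortably inside the single-copy regions
  pmin(ext, pmax(0L, min(singlecopy) %/% 3L))
}

# Guard bases must be pairwise distinct within an equal-extension-length group
# and differ from the master-extension continuation base (when one exists).
check_guard_feasible <- function(ext, side) {
  if (max(ext) == 0L) return(invisible(TRUE))
  for (len in unique(ext)) {
    size <- sum(ext == len)
    limit <- if (len < max(ext)) 3L else 4L
    if (size > limit)
      stop_mitodyn("infeasible spec: ", size, " copies share a ", side,
                   " extension of length ", len,
                   "; guard bases cannot be made pairwise distinct")
  }
  invisible(TRUE)
}

#' Generate a circular genome with a planted repeat family and ground truth
#'
#' Realises a [genome_spec()]: a random circular genome containing exactly
#' `n_repeats` identical copies of a random core sequence in direct
#' orientation, each flanked by its planted extensions (identical across the
#' copies that share them), distinct single-copy regions, and enzyme
#' recognition sites only at the planted offsets.  Construction screening
#' guarantees that no exact repeat of length `repeat_floor` or more occurs
#' other than the planted family, and that the enzyme site occurs nowhere but
#' the planted positions.
#'
#' @param spec a [genome_spec()].
#' @return A list with components `genome` (class `circular_genome`: `name`,
#'   `seq`, `length`, `circular`) and `truth` (class `genome_truth`: planted
#'   core/extension/single-copy intervals in 0-based half-open circular
#'   coordinates, planted extension lengths, and planted enzyme site
#'   positions).
#' @examples
#' gt <- make_genome(genome_spec(n_repeats = 3, core_length = 300,
#'                               singlecopy_lengths = rep(800, 3), seed = 7))
#' gt$genome
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, make_genome_impl(spec))
}

make_genome_impl <- function(spec) {
  n <- spec$n_repeats
  core_len <- spec$core_length
  extL <- spec$extension_left
  extR <- spec$extension_right
  gaps <- spec$singlecopy_lengths
  gc <- spec$gc_content
  site <- spec$enzyme_site
  nxt <- c(seq_len(n)[-1L], 1L)
  maxL <- max(extL); maxR <- max(extR)

  core <- scrub_site(random_dna(core_len, gc), site)
  ML <- if (maxL > 0L) scrub_site(random_dna(maxL, gc), site) else ""
  MR <- if (maxR > 0L) scrub_site(random_dna(maxR, gc), site) else ""
  ulen <- gaps - extR - extL[nxt]
  U <- vapply(ulen, function(m) scrub_site(random_dna(m, gc), site), "")

  # --- guard bases ---------------------------------------------------------
  # Right side: first base of U_c must differ from MR[extR[c] + 1] (the master
  # continuation) and from the first bases of other copies with equal extR.
  U <- place_guards(U, extR, MR, at_start = TRUE)
  # Left side: last base of U_c guards the left extension of copy c+1;
  # group by extL[nxt], continuation base is ML[maxL - extL].
  U <- place_guards(U, extL[nxt], ML, at_start = FALSE)

  # --- plant enzyme sites --------------------------------------------------
  site_upos <- NULL
  if (!is.null(spec$site_offsets)) {
    site_upos <- spec$site_offsets - extR  # 0-based offset within U_c
    sl <- nchar(site)
    for (c in seq_len(n)) {
      substr(U[c], site_upos[c] + 1L, site_upos[c] + sl) <- site
    }
  }

  assemble <- function(core, MR, ML, U) {
    pieces <- character(0L)
    for (c in seq_len(n)) {
      pieces <- c(pieces, core,
                  if (extR[c] > 0L) substr(MR, 1L, extR[c]) else "",
                  U[c],
                  if (extL[nxt[c]] > 0L) substr(ML, maxL - extL[nxt[c]] + 1L, maxL) else "")
    }
    paste(pieces, collapse = "")
  }

  # genome coordinates (0-based): core c starts at P[c]
  P <- integer(n)
  for (c in seq_len(n)[-1L]) P[c] <- P[c - 1L] + core_len + gaps[c - 1L]
  L <- sum(gaps) + n * core_len
  gap_start <- P + core_len
  planted_sites <- if (is.null(site_upos)) integer(0L) else
    gap_start + extR + site_upos

  # positions that later screening passes must not touch
  protected <- logical(L)
  if (length(planted_sites)) {
    sl <- nchar(site)
    for (p in planted_sites) protected[(p:(p + sl - 1L)) %% L + 1L] <- TRUE
  }
  for (c in seq_len(n)) {           # guard bases
    ustart <- gap_start[c] + extR[c]
    protected[ustart + 1L] <- TRUE
    protected[ustart + ulen[c]] <- TRUE  # last base of U_c (1-based index)
  }
  # master-extension continuation bases back the guard construction
  protML <- logical(max(maxL, 1L)); protMR <- logical(max(maxR, 1L))
  for (len in unique(extR)) if (maxR > 0L && len < maxR) protMR[len + 1L] <- TRUE
  for (len in unique(extL)) if (maxL > 0L && len < maxL) protML[maxL - len] <- TRUE

  # mutate genome position q (0-based) at component level, keeping repeat
  # copies identical; returns TRUE on success
  mutate_component <- function(q) {
    if (protected[q + 1L]) return(FALSE)
    for (c in seq_len(n)) {
      d <- (q - P[c]) %% L
      if (d < core_len) {                      # inside core copy c
        old <- substr(core, d + 1L, d + 1L)
        substr(core, d + 1L, d + 1L) <<- sample(setdiff(DNA_BASES, old), 1L)
        return(TRUE)
      }
      g <- d - core_len                        # offset into gap c
      if (g < 0L || g >= gaps[c]) next
      if (g < extR[c]) {                       # right master extension
        if (protMR[g + 1L]) return(FALSE)
        old <- substr(MR, g + 1L, g + 1L)
        substr(MR, g + 1L, g + 1L) <<- sample(setdiff(DNA_BASES, old), 1L)
        return(TRUE)
      }
      if (g < extR[c] + ulen[c]) {             # unique region
        upos <- g - extR[c] + 1L
        old <- substr(U[c], upos, upos)
        substr(U[c], upos, upos) <<- sample(setdiff(DNA_BASES, old), 1L)
        return(TRUE)
      }
      mpos <- maxL - (gaps[c] - g)             # left master extension (0-based)
      if (protML[mpos + 1L]) return(FALSE)
      old <- substr(ML, mpos + 1L, mpos + 1L)
      substr(ML, mpos + 1L, mpos + 1L) <<- sample(setdiff(DNA_BASES, old), 1L)
      return(TRUE)
    }
    FALSE
  }

  genome <- assemble(core, MR, ML, U)

  # --- screening loop: stray enzyme sites and unplanned repeats ------------
  for (iter in seq_len(60L)) {
    span <- NULL
    if (!is.null(site)) {
      occ <- circ_occurrences(genome, site)
      extra <- setdiff(occ, planted_sites)
      if (length(extra))
        span <- (extra[1L] + seq_len(nchar(site)) - 1L) %% L
    }
    if (is.null(span)) {
      off <- unexpected_dup_windows(genome, P, extL, extR, core_len,
                                    spec$repeat_floor)
      if (length(off))
        span <- (off[1L] + seq_len(spec$repeat_floor) - 1L) %% L
    }
    if (is.null(span)) break
    # prefer mutating in a unique region, then anywhere permissible
    in_unique <- vapply(span, function(q)
      any(q >= gap_start + extR & q < gap_start + extR + ulen), TRUE)
    fixed <- FALSE
    for (q in c(span[in_unique], span[!in_unique])) {
      if (mutate_component(q)) { fixed <- TRUE; break }
    }
    if (!fixed)
      stop_mitodyn("screening failed: could not remove an unplanned repeat or ",
                   "enzyme site without touching planted structure")
    genome <- assemble(core, MR, ML, U)
    if (iter == 60L)
      stop_mitodyn("screening did not converge; relax the spec")
  }

  genome_obj <- structure(list(name = "synthetic_circular_genome",
                               seq = genome, length = L, circular = TRUE),
                          class = "circular_genome")
  copies <- data.frame(copy = seq_len(n), start = P, end = P + core_len)
  ext_iv <- data.frame(
    copy = rep(seq_len(n), 2L),
    side = rep(c("left", "right"), each = n),
    start = c((P - extL) %% L, gap_start),
    end = c((P - extL) %% L + extL, gap_start + extR),
    length = c(extL, extR))
  singlecopy <- data.frame(id = seq_len(n), start = gap_start,
                           end = gap_start + gaps)
  unique_iv <- data.frame(id = seq_len(n), start = gap_start + extR,
                          end = gap_start + extR + ulen)
  truth <- structure(list(
    n_repeats = n, core_length = core_len, genome_length = L,
    repeat_copy_intervals = copies,
    extension_intervals = ext_iv,
    extension_left = extL, extension_right = extR,
    singlecopy_intervals = singlecopy,
    unique_intervals = unique_iv,
    enzyme_site = site, site_positions = planted_sites,
    site_offsets = spec$site_offsets,
    seed = spec$seed
  ), class = "genome_truth")
  list(genome = genome_obj, truth = truth)
}

# Replace interior bases of any occurrence of `site` so none remain.
scrub_site <- function(seq, site) {
  if (is.null(site) || nchar(seq) < nchar(site)) return(seq)
  repeat {
    hit <- regexpr(site, seq, fixed = TRUE)
    if (hit < 0L) return(seq)
    mid <- hit + nchar(site) %/% 2L
    old <- substr(seq, mid, mid)
    substr(seq, mid, mid) <- sample(setdiff(DNA_BASES, old), 1L)
  }
}

# Set guard bases at the start (right side) or end (left side) of each unique
# region.  `ext` gives the group key per gap; `master` the master extension.
place_guards <- function(U, ext, master, at_start) {
  maxlen <- max(ext)
  if (maxlen == 0L && length(U) > 4L) return(U)  # best effort; documented
  for (len in unique(ext)) {
    idx <- which(ext == len)
    forbidden <- character(0L)
    if (maxlen > 0L && len < maxlen) {
      forbidden <- if (at_start) substr(master, len + 1L, len + 1L)
      else substr(master, maxlen - len, maxlen - len)
    }
    for (c in idx) {
      pos <- if (at_start) 1L else nchar(U[c])
      cur <- substr(U[c], pos, pos)
      if (cur %in% forbidden) {
        allowed <- setdiff(DNA_BASES, forbidden)
        cur <- sample(allowed, 1L)
        substr(U[c], pos, pos) <- cur
      }
      forbidden <- c(forbidden, cur)
    }
  }
  U
}

# All occurrence start positions (0-based, < L) of `pat` on the circular seq.
circ_occurrences <- function(seq, pat) {
  L <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, min(L, nchar(pat) - 1L)))
  m <- gregexpr(pat, doubled, fixed = TRUE)[[1L]]
  if (m[1L] < 0L) return(integer(0L))
  starts <- as.integer(m) - 1L
  sort(unique(starts[starts < L]))
}

# Overlapping occurrences need a manual scan (gregexpr reports disjoint hits);
# sites here are short and non-self-overlapping in practice, so gregexpr is
# adequate for scrubbing; planted-site bookkeeping uses exact positions.

# Window starts (0-based) of duplicated `k`-windows not explained by the
# planted repeat family (same offset in distinct copies, inside core+ext).
unexpected_dup_windows <- function(genome, P, extL, extR, core_len, k) {
  L <- nchar(genome)
  if (L < 2L * k) return(integer(0L))
  doubled <- paste0(genome, substr(genome, 1L, k - 1L))
  w <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  idx <- match(w, w)
  tab <- tabulate(idx, nbins = L)
  dup <- which(tab[idx] >= 2L)           # all positions in duplicated groups
  if (length(dup) == 0L) return(integer(0L))
  pos0 <- dup - 1L
  n <- length(P)
  copyof <- rep(NA_integer_, length(pos0))
  off <- rep(NA_integer_, length(pos0))
  for (c in seq_len(n)) {
    s <- P[c] - extL[c]
    d <- (pos0 - s) %% L
    inside <- is.na(copyof) & (d + k <= extL[c] + core_len + extR[c])
    copyof[inside] <- c
    off[inside] <- d[inside] - extL[c]
  }
  grp <- idx[dup]
  ok <- vapply(split(seq_along(pos0), grp), function(ii) {
    if (anyNA(copyof[ii])) return(FALSE)
    if (anyDuplicated(copyof[ii]) > 0L) return(FALSE)
    length(unique(off[ii])) == 1L
  }, TRUE)
  bad_groups <- names(ok)[!ok]
  if (length(bad_groups) == 0L) return(integer(0L))
  sort(pos0[grp %in% as.integer(bad_groups)])
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp%s\n", x$name, x$length,
              if (isTRUE(x$circular)) " (circular)" else ""))
  invisible(x)
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf(
    "<genome_truth> %d-copy repeat, core %d bp, genome %d bp, %d planted site(s)\n",
    x$n_repeats, x$core_length, x$genome_length, length(x$site_positions)))
  invisible(x)
}
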