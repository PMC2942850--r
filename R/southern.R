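#' In-silico restriction digest of a linear or circular molecule
#'
#' Cuts at every exact occurrence of the recognition site (cut point taken at
#' the site start) and returns the fragment lengths.  Fragment lengths always
#' sum to the molecule length.
#'
#' @param seq molecule sequence.
#' @param enzyme_site recognition sequence (>= 4 nt).
#' @param circular treat the molecule as circular (a single cut linearises
#'   it; no cut returns the full length as one fragment).
#' @return Integer vector of fragment lengths (5' to 3').
#' @export
digest_molecule <- function(seq, enzyme_site, circular = FALSE) {
  enzyme_site <- toupper(enzyme_site)
  if (nchar(enzyme_site) < 4L) stop_mitodyn("enzyme site must be >= 4 nt")
  len <- nchar(seq)
  if (circular) {
    cuts <- circ_occurrences(seq, enzyme_site)
    if (length(cuts) == 0L) return(len)
    return(as.integer(diff(c(cuts, cuts[1L] + len))))
  }
  m <- gregexpr(enzyme_site, seq, fixed = TRUE)[[1L]]
  cuts <- if (m[1L] < 0L) integer(0L) else as.integer(m) - 1L
  as.integer(diff(c(0L, cuts, len)))
}

#' Predict virtual Southern blot bands over an equilibrium molecule pool
#'
#' Emulates the hybridisation experiment that diagnoses recombinational
#' equilibrium: each junction molecule of the pool is digested at every exact
#' occurrence of the enzyme site, and the fragment containing the probe is
#' recorded.  Molecules sharing the probe-side flank but differing only beyond
#' their nearest cut sites collapse to one band, so with one distinctly
#' placed site per single-copy region a probe in one flank of an n-copy
#' repeat yields n distinct bands.
#'
#' @param pool a `molecule_pool` (carries its genome and ground truth).
#' @param probe 0-based half-open genome interval `c(start, end)`; must lie
#'   within a single-copy (unique) region — a probe in the repeat core or a
#'   shared extension would hybridise non-specifically.
#' @param enzyme_site recognition sequence (default the pool genome's planted
#'   site).
#' @return A `virtual_blot`: `fragments` (per hybridising molecule: flank ids
#'   and fragment length), `bands` (sorted distinct lengths), `probe`,
#'   `enzyme_site`.
#' @export
virtual_southern <- function(pool, probe, enzyme_site = NULL) {
  stopifnot(inherits(pool, "molecule_pool"))
  genome <- attr(pool, "genome")
  truth <- attr(pool, "truth")
  if (is.null(enzyme_site)) enzyme_site <- truth$enzyme_site
  if (is.null(enzyme_site)) stop_mitodyn("no enzyme site given or planted")
  enzyme_site <- toupper(enzyme_site)
  if (nchar(enzyme_site) < 4L) stop_mitodyn("enzyme site must be >= 4 nt")
  probe <- as.integer(probe)
  if (length(probe) != 2L || probe[2L] <= probe[1L])
    stop_mitodyn("probe must be c(start, end), 0-based half-open, end > start")
  L <- genome$length

  # probe must be single-copy: reject overlap with any core or extension
  ci <- truth$repeat_copy_intervals
  for (i in seq_len(nrow(ci)))
    if (circ_intervals_overlap(probe[1L], probe[2L], ci$start[i], ci$end[i], L))
      stop_mitodyn("probe overlaps repeat core copy ", ci$copy[i],
                   "; it would hybridise non-specifically")
  ei <- truth$extension_intervals
  for (i in seq_len(nrow(ei)))
    if (ei$length[i] > 0L &&
        circ_intervals_overlap(probe[1L], probe[2L], ei$start[i], ei$end[i], L))
      stop_mitodyn("probe overlaps a shared repeat extension (copy ",
                   ei$copy[i], ", ", ei$side[i], " side)")
  # probe must not overlap a cut site
  for (p in truth$site_positions)
    if (circ_intervals_overlap(probe[1L], probe[2L], p,
                               p + nchar(enzyme_site), L))
      stop_mitodyn("probe interval [", probe[1L], ", ", probe[2L],
                   ") overlaps the enzyme site planted at position ", p)

  probe_seq <- circ_substr(genome$seq, probe[1L] %% L, probe[1L] %% L + probe[2L] - probe[1L])

  hits <- regexpr(probe_seq, pool$seq, fixed = TRUE)
  frag <- data.frame(left_id = integer(0), right_id = integer(0),
                     fragment_length = integer(0))
  for (i in which(hits > 0L)) {
    a <- as.integer(hits[i]) - 1L          # 0-based probe start in molecule
    b <- a + nchar(probe_seq)
    m <- gregexpr(enzyme_site, pool$seq[i], fixed = TRUE)[[1L]]
    cuts <- if (m[1L] < 0L) integer(0L) else as.integer(m) - 1L
    if (any(cuts < b & cuts + nchar(enzyme_site) > a))
      stop_mitodyn("probe overlaps a cut site within molecule ", i)
    lc <- cuts[cuts <= a]; rc <- cuts[cuts >= b]
    if (length(lc) == 0L || length(rc) == 0L)
      stop_mitodyn("molecule ", i, " (flanks ", pool$left_id[i], "/",
                   pool$right_id[i], ") lacks a cut site on one side of the ",
                   "probe; increase the molecule span or plant more sites")
    frag <- rbind(frag, data.frame(left_id = pool$left_id[i],
                                   right_id = pool$right_id[i],
                                   fragment_length = min(rc) - max(lc)))
  }
  frag$fragment_length <- as.integer(frag$fragment_length)
  structure(list(fragments = frag,
                 bands = sort(unique(frag$fragment_length)),
                 probe = probe, enzyme_site = enzyme_site),
            class = "virtual_blot")
}

#' @export
print.virtual_blot <- function(x, ...) {
  cat(sprintf("<virtual_blot> %d hybridising molecule(s), %d distinct band(s): %s\n",
              nrow(x$fragments), length(x$bands),
              paste(x$bands, collapse = ", ")))
  invisible(x)
}
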