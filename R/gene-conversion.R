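#' Condense an alignment to the polymorphic profile of a sequence pair
#'
#' Keeps the alignment columns that are polymorphic (not all sequences
#' identical) and free of gaps in both members of the designated pair, and
#' records for each such site whether the pair matches.  Columns where the
#' pair agrees while another sequence differs are *match* sites — the raw
#' material of a conversion signal; columns where the pair differs are
#' *mismatch* sites.
#'
#' @param alignment a `conversion_alignment`, or a named character vector of
#'   equal-length aligned sequences (gap symbol `-`).
#' @param pair character vector of two sequence labels
#'   (default `c("recipient", "donor")`).
#' @return A `polymorphic_profile`: `columns` (0-based alignment column
#'   indices, strictly increasing), `match` (logical per site), `pair`,
#'   `n_columns` (alignment width).
#' @export
condense_alignment <- function(alignment, pair = c("recipient", "donor")) {
  seqs <- if (inherits(alignment, "conversion_alignment")) alignment$sequences
  else alignment
  if (is.null(names(seqs)) || length(seqs) < 2L)
    stop_mitodyn("alignment must be >= 2 named sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop_mitodyn("aligned sequences must have equal length")
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stop_mitodyn("pair must be two distinct labels")
  if (!all(pair %in% names(seqs)))
    stop_mitodyn("unknown sequence label(s): ",
                 paste(setdiff(pair, names(seqs)), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  a <- mat[pair[1L], ]; b <- mat[pair[2L], ]
  no_gap <- a != "-" & b != "-"
  polymorphic <- colSums(mat != mat[rep(1L, nrow(mat)), , drop = FALSE]) > 0L
  keep <- which(no_gap & polymorphic)
  structure(list(columns = keep - 1L, match = a[keep] == b[keep],
                 pair = pair, n_columns = ncol(mat)),
            class = "polymorphic_profile")
}

#' @export
print.polymorphic_profile <- function(x, ...) {
  cat(sprintf("<polymorphic_profile> %s vs %s: %d polymorphic sites (%d match, %d mismatch)\n",
              x$pair[1L], x$pair[2L], length(x$columns), sum(x$match),
              sum(!x$match)))
  invisible(x)
}

# build a profile directly from match/mismatch states (mostly for simulation)
profile_from_states <- function(match, columns = seq_along(match) - 1L) {
  structure(list(columns = as.integer(columns), match = as.logical(match),
                 pair = c("a", "b"), n_columns = max(columns) + 1L),
            class = "polymorphic_profile")
}

#' Maximal-scoring conversion fragments of a polymorphic profile
#'
#' Scores each polymorphic site +1 (pair match) or `-g` (mismatch) and
#' returns all maximal-scoring segments in the standard sense (Ruzzo-Tompa):
#' contiguous runs whose score cannot be improved by extension or trimming.
#' A long run of matching sites between mismatch-dominated flanks — the
#' footprint of a conversion tract — surfaces as a high-scoring fragment.
#'
#' @param profile a `polymorphic_profile`.
#' @param mismatch_cost the mismatch penalty g >= 0 (the classic setting is
#'   g = 1).
#' @return A `conversion_fragments` data frame, sorted by score descending
#'   (ties by leftmost start): `site_start`/`site_end` (1-based indices into
#'   the profile, inclusive), `col_start`/`col_end` (0-based half-open
#'   alignment columns), `sites`, `matches`, `mismatches`, `score`.
#' @export
max_scoring_fragments <- function(profile, mismatch_cost = 1) {
  stopifnot(inherits(profile, "polymorphic_profile"))
  g <- mismatch_cost
  if (g < 0) stop_mitodyn("mismatch_cost must be >= 0")
  x <- ifelse(profile$match, 1, -g)
  segs <- ruzzo_tompa(x)
  out <- data.frame(site_start = integer(0), site_end = integer(0),
                    col_start = integer(0), col_end = integer(0),
                    sites = integer(0), matches = integer(0),
                    mismatches = integer(0), score = numeric(0))
  if (length(segs)) {
    out <- do.call(rbind, lapply(segs, function(s) {
      idx <- s[1L]:s[2L]
      data.frame(site_start = s[1L], site_end = s[2L],
                 col_start = profile$columns[s[1L]],
                 col_end = profile$columns[s[2L]] + 1L,
                 sites = length(idx),
                 matches = sum(profile$match[idx]),
                 mismatches = sum(!profile$match[idx]),
                 score = sum(x[idx]))
    }))
    out <- out[order(-out$score, out$site_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("conversion_fragments", "data.frame")
  attr(out, "mismatch_cost") <- g
  out
}

# Ruzzo-Tompa all maximal scoring subsequences; returns list of c(start, end)
# (1-based, inclusive).  Segments begin and end on positive scores.
ruzzo_tompa <- function(x) {
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  Ls <- numeric(0); Rs <- numeric(0)
  cum <- 0
  for (k in seq_len(n)) {
    prev <- cum
    cum <- cum + x[k]
    if (x[k] <= 0) next
    s <- k; e <- k; Lk <- prev; Rk <- cum
    repeat {
      j <- which(Ls < Lk)
      j <- if (length(j)) max(j) else 0L
      if (j == 0L) {
        # no list entry with smaller left score: current is (for now) maximal
        starts <- c(starts, s); ends <- c(ends, e)
        Ls <- c(Ls, Lk); Rs <- c(Rs, Rk)
        break
      }
      if (Rs[j] >= Rk) {
        starts <- c(starts, s); ends <- c(ends, e)
        Ls <- c(Ls, Lk); Rs <- c(Rs, Rk)
        break
      }
      # merge with entry j and everything after it
      s <- starts[j]; Lk <- Ls[j]
      keep <- seq_len(j - 1L)
      starts <- starts[keep]; ends <- ends[keep]
      Ls <- Ls[keep]; Rs <- Rs[keep]
    }
  }
  segs <- Map(c, starts, ends)
  # trim trailing non-positive tail inside each segment (keep max prefix)
  lapply(segs, function(se) {
    idx <- se[1L]:se[2L]
    cs <- cumsum(x[idx])
    best <- which.max(cs)
    c(se[1L], se[1L] + best - 1L)
  })
}

#' Permutation p-values for conversion fragments
#'
#' The null distribution of the *maximum* fragment score is obtained by
#' uniformly permuting the order of the profile's match/mismatch states
#' `n_perm` times (the counts are held fixed, so the null depends only on
#' composition and order).  Each observed fragment gets
#' `p = (1 + #\{null max >= score\}) / (n_perm + 1)`.
#'
#' @param profile a `polymorphic_profile`.
#' @param mismatch_cost mismatch penalty g.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return The `conversion_fragments` table with a `p.value` column; the null
#'   maxima are attached as attribute `"null_max"`.
#' @export
conversion_pvalue <- function(profile, mismatch_cost = 1, n_perm = 999L,
                              seed = 1L) {
  stopifnot(inherits(profile, "polymorphic_profile"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop_mitodyn("n_perm must be >= 99")
  frags <- max_scoring_fragments(profile, mismatch_cost)
  x <- ifelse(profile$match, 1, -mismatch_cost)
  m <- length(x)
  null_max <- with_seed(seed, {
    perm <- matrix(0, m, n_perm)
    for (b in seq_len(n_perm)) perm[, b] <- x[sample.int(m)]
    cs <- apply(perm, 2L, cumsum)
    if (m == 1L) cs <- matrix(cs, nrow = 1L)
    low <- apply(rbind(0, cs[-m, , drop = FALSE]), 2L, cummin)
    pmax(apply(cs - low, 2L, max), 0)
  })
  frags$p.value <- vapply(frags$score, function(s)
    (1 + sum(null_max >= s)) / (n_perm + 1), 1)
  attr(frags, "null_max") <- null_max
  attr(frags, "n_perm") <- n_perm
  frags
}

#' Overlap of a conversion fragment with annotation features
#'
#' Reports all features intersecting the fragment's alignment-column
#' interval, with the overlap expressed as a fraction of the feature and of
#' the fragment (e.g. to ask whether a tract coincides with an rRNA helix).
#'
#' @param fragment one row of a `conversion_fragments` table (or any object
#'   with `col_start`/`col_end`).
#' @param features data frame with columns `start`, `end` (0-based half-open
#'   alignment columns) and optionally `name`.
#' @return Data frame of overlapping features with `overlap`, `feature_frac`,
#'   `fragment_frac`.
#' @export
tract_feature_overlap <- function(fragment, features) {
  fs <- fragment$col_start[1L]; fe <- fragment$col_end[1L]
  if (is.null(features$name)) features$name <- paste0("feature_", seq_len(nrow(features)))
  ov <- pmin(features$end, fe) - pmax(features$start, fs)
  keep <- which(ov > 0)
  data.frame(name = features$name[keep],
             start = features$start[keep], end = features$end[keep],
             overlap = ov[keep],
             feature_frac = ov[keep] / (features$end[keep] - features$start[keep]),
             fragment_frac = ov[keep] / (fe - fs))
}
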