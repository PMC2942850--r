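#' Count distinct master-circle conformations for an n-copy direct repeat
#'
#' A genome with n identical direct repeat copies separated by n single-copy
#' segments admits `(n-1)!` distinct cyclic orders of the segments:
#' conformations are counted up to rotation but *not* reflection, because
#' direct repeats fix the orientation of every segment.  For n = 6 this gives
#' 120 conformations.
#'
#' @param n number of repeat copies (>= 1).
#' @return The conformation count, `(n-1)!`.
#' @export
count_master_circles <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_mitodyn("n must be >= 1")
  factorial(n - 1L)
}

#' Enumerate distinct master-circle conformations
#'
#' Lists all cyclic orders of the n single-copy segments, canonicalised by
#' rotating segment 1 to the front (direct repeats fix orientation, so no
#' reflection dedup applies).  Enumeration is capped because the list grows as
#' `(n-1)!`; use [count_master_circles()] beyond the cap.
#'
#' @param n number of repeat copies.
#' @param cap refuse enumeration above this n (default 8).
#' @return A list of integer vectors, each a conformation's segment order
#'   starting at segment 1; length `(n-1)!`, no duplicates under rotation.
#' @export
enumerate_master_circles <- function(n, cap = 8L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_mitodyn("n must be >= 1")
  if (n > cap)
    stop_mitodyn("n = ", n, " exceeds the enumeration cap (", cap,
                 "); use count_master_circles() for the count only")
  if (n == 1L) return(list(1L))
  perms <- permutations_of(seq_len(n)[-1L])
  lapply(perms, function(p) c(1L, p))
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Enumerate all ordered flanking pairs of an n-copy repeat
#'
#' Recombination among n repeat copies can juxtapose any "left" single-copy
#' flank with any "right" flank, giving n^2 ordered pairs (36 for n = 6).
#'
#' @param n number of repeat copies.
#' @return A data frame with columns `left_id`, `right_id` (n^2 rows).
#' @export
enumerate_flanking_pairs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_mitodyn("n must be >= 1")
  g <- expand.grid(right_id = seq_len(n), left_id = seq_len(n))
  data.frame(left_id = g$left_id, right_id = g$right_id)
}

#' Count subgenomic circles with up to k_max repeat loci
#'
#' A subgenomic circle carries a k-subset of the n single-copy segments
#' (1 <= k <= k_max < n), in any cyclic order: the count is
#' `sum over k of choose(n, k) * (k-1)!`.  For n = 6, k_max = 5 this gives
#' 295 — the "hundreds" of subgenomic circles an actively recombining 6-copy
#' family can generate.
#'
#' @param n number of repeat copies.
#' @param k_max largest number of repeat loci per subgenomic circle;
#'   must be < n (k = n is the master-circle class).
#' @return The subgenomic circle count.
#' @export
count_subgenomic_circles <- function(n, k_max) {
  n <- as.integer(n); k_max <- as.integer(k_max)
  if (is.na(n) || n < 2L) stop_mitodyn("n must be >= 2")
  if (is.na(k_max) || k_max < 1L || k_max >= n)
    stop_mitodyn("k_max must satisfy 1 <= k_max < n (k = n is the master circle)")
  sum(vapply(seq_len(k_max), function(k) choose(n, k) * factorial(k - 1L), 1))
}

#' Classify read pairs into flanking-pair support counts
#'
#' Each read is located by exact full-length matching against the circular
#' reference (forward strand; the reverse read is reverse-complemented first)
#' and must match at exactly one position — reads wholly inside the repeat
#' core or a shared extension are multi-mapping and their pair is skipped.  A
#' uniquely mapped pair supports flanking pair (i, j) when the forward read
#' anchors in the left flank of copy i, the reverse read in the right flank of
#' copy j, and the implied span — from the forward read start, through one
#' core copy (plus applicable extensions), to the reverse read end — lies
#' within the insert bounds.  Pairs contained in a single single-copy region
#' without crossing a core are consistent but uninformative.
#'
#' @param pairs a `read_pairs` data frame (see [make_read_pairs()]).
#' @param genome the `circular_genome` reference.
#' @param family the repeat family (`repeat_family`, e.g. from
#'   [find_repeat_families()] or [family_from_truth()]).
#' @param insert_bounds c(min, max) allowed insert/span in nt.
#' @param anchor_k k-mer width used to seed exact read location (internal
#'   performance knob).
#' @param index optional precomputed [genome_kmer_index()] for repeated calls.
#' @return A list of class `pair_support`: `counts` (n x n matrix of
#'   supporting pair counts, rows = left flank), `detail` (per-pair
#'   classification), `n_uninformative`, `n_skipped`, `n_conflict`.
#' @export
support_from_read_pairs <- function(pairs, genome, family,
                                    insert_bounds = c(4000L, 6500L),
                                    anchor_k = 32L, index = NULL) {
  stopifnot(inherits(genome, "circular_genome"), inherits(family, "repeat_family"))
  L <- genome$length
  n <- family$n_copies
  P <- family$copies$start
  core_len <- family$core_length
  ordP <- order(P)
  P <- P[ordP]                       # copies in genome order; ids follow order
  imin <- insert_bounds[1L]; imax <- insert_bounds[2L]

  counts <- matrix(0L, n, n, dimnames = list(left = seq_len(n), right = seq_len(n)))
  res <- list(counts = counts, detail = NULL, n_uninformative = 0L,
              n_skipped = 0L, n_conflict = 0L)
  class(res) <- "pair_support"
  if (nrow(pairs) == 0L) return(res)

  if (is.null(index)) index <- genome_kmer_index(genome, anchor_k)
  pos1 <- locate_reads_unique(pairs$read1, genome, index)
  pos2 <- locate_reads_unique(revcomp_vec(pairs$read2), genome, index)

  m <- nrow(pairs)
  cls <- rep("skipped", m)
  left_id <- rep(NA_integer_, m); right_id <- rep(NA_integer_, m)
  ok <- !is.na(pos1) & !is.na(pos2)

  rl <- nchar(pairs$read2[1L])
  e2 <- (pos2 + rl) %% L                 # exclusive end of the reverse read

  # segment of a position: copy c* minimising (p - P_c) mod L; inside core if
  # that distance < core length, else in the gap following copy c*
  seg <- function(p) {
    d <- outer(p, P, function(a, b) (a - b) %% L)
    cstar <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_along(p), cstar)]
    list(copy = cstar, off = dmin, in_core = dmin < core_len)
  }
  s1 <- seg(pos1[ok])
  s2 <- seg((e2[ok] - 1L) %% L)

  informative <- !s1$in_core & !s2$in_core
  g <- s1$copy            # forward read sits in the gap after core g
  h <- s2$copy            # reverse read end sits in the gap after core h

  # uninformative: both anchors in the same gap, forward before reverse,
  # nothing crossed, and the direct placement is a plausible insert (a
  # same-gap placement with an impossibly short span is NOT consistent — the
  # pair must straddle a repeat copy and is classified by the junction rule)
  d_direct <- (e2[ok] - pos1[ok]) %% L
  to_gap_end <- (P[g %% n + 1L] - pos1[ok]) %% L   # distance to next core start
  same_gap <- informative & g == h & d_direct <= to_gap_end &
    d_direct >= imin & d_direct <= imax

  a <- g %% n + 1L        # candidate left flank: the copy following gap g
  b <- h                  # candidate right flank: the copy preceding gap h
  gap_start_b <- (P[b] + core_len) %% L
  span <- ((P[a] - pos1[ok]) %% L) + core_len + ((e2[ok] - gap_start_b) %% L)
  supported <- informative & !same_gap & span >= imin & span <= imax

  okk <- which(ok)
  cls[okk] <- ifelse(supported, "support",
                     ifelse(informative & !same_gap, "conflict", "uninformative"))
  left_id[okk[supported]] <- a[supported]
  right_id[okk[supported]] <- b[supported]

  tab <- table(factor(left_id[okk[supported]], levels = seq_len(n)),
               factor(right_id[okk[supported]], levels = seq_len(n)))
  counts[] <- as.integer(tab)
  if (any(is.na(pos1) | is.na(pos2)))
    message(sum(is.na(pos1) | is.na(pos2)),
            " read pair(s) skipped (no unique exact match)")

  res$counts <- counts
  res$detail <- data.frame(class = cls, left_id = left_id, right_id = right_id)
  res$n_uninformative <- sum(cls == "uninformative")
  res$n_skipped <- sum(cls == "skipped")
  res$n_conflict <- sum(cls == "conflict")
  res
}

#' @export
print.pair_support <- function(x, ...) {
  n_sup <- sum(x$counts)
  cat(sprintf(
    "<pair_support> %d supporting pairs over %d flanking pairs (%d with >= 2); %d uninformative, %d skipped, %d conflicting\n",
    n_sup, length(x$counts), sum(x$counts >= 2L), x$n_uninformative,
    x$n_skipped, x$n_conflict))
  invisible(x)
}

#' Number of flanking pairs reaching an evidentiary support threshold
#'
#' @param support a `pair_support` object.
#' @param min_support required number of independent subclones (default 2,
#'   the "supported by multiple subclones" bar).
#' @return Count of flanking pairs with at least `min_support` read pairs.
#' @export
supported_pairs <- function(support, min_support = 2L) {
  stopifnot(inherits(support, "pair_support"))
  sum(support$counts >= min_support)
}

#' Precompute a k-mer position index of a circular genome
#'
#' Maps every k-mer of the doubled sequence to its 0-based start positions;
#' used to seed exact read location in [support_from_read_pairs()].
#'
#' @param genome a `circular_genome`.
#' @param k k-mer width (default 32).
#' @return An opaque index object.
#' @export
genome_kmer_index <- function(genome, k = 32L) {
  seq <- genome$seq; L <- genome$length
  doubled <- paste0(seq, substr(seq, 1L, k - 1L))
  kmers <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  idx <- split(0:(L - 1L), kmers)
  structure(list(map = idx, k = k, doubled = paste0(seq, seq)), class = "genome_kmer_index")
}

# unique exact forward-strand location (0-based start) of each read, NA if
# absent or multi-mapping
locate_reads_unique <- function(reads, genome, index) {
  L <- genome$length
  k <- index$k
  rl <- nchar(reads)
  pref <- substr(reads, 1L, k)
  cand <- index$map[pref]                      # list; NULL where prefix absent
  nc <- lengths(cand)
  ridx <- rep(seq_along(reads), nc)
  pp <- unlist(cand, use.names = FALSE)
  if (length(pp) == 0L) return(rep(NA_integer_, length(reads)))
  full <- substring(index$doubled, pp + 1L, pp + rl[ridx])
  hit <- full == reads[ridx]
  ridx <- ridx[hit]; pp <- pp[hit]
  nhit <- tabulate(ridx, nbins = length(reads))
  out <- rep(NA_integer_, length(reads))
  uniq <- nhit == 1L
  out[ridx[uniq[ridx]]] <- pp[uniq[ridx]]
  out
}

#' Chi-square test for recombinational equilibrium
#'
#' Goodness-of-fit of flanking-pair support counts against the uniform
#' expectation (all n^2 pairs equally frequent — "recombinational
#' equilibrium"), with df = n^2 - 1, plus a normalised Shannon evenness index
#' (1 = perfectly even).
#'
#' @param support_counts an n x n count matrix (e.g. `$counts` of a
#'   `pair_support`) or a count vector over all flanking pairs.
#' @return A list of class `equilibrium_test`: `statistic`, `df`, `p.value`,
#'   `evenness`, `total`.
#' @export
equilibrium_test <- function(support_counts) {
  if (inherits(support_counts, "pair_support"))
    support_counts <- support_counts$counts
  x <- as.numeric(support_counts)
  m <- length(x)
  N <- sum(x)
  if (N <= 0) stop_mitodyn("total support count is zero; no test possible")
  e <- N / m
  stat <- sum((x - e)^2 / e)
  df <- m - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  pr <- x[x > 0] / N
  evenness <- if (m > 1L) -sum(pr * log(pr)) / log(m) else 1
  structure(list(statistic = stat, df = df, p.value = p,
                 evenness = evenness, total = N),
            class = "equilibrium_test")
}

#' @export
print.equilibrium_test <- function(x, ...) {
  cat(sprintf(
    "Recombinational equilibrium test\n  X-squared = %.3f, df = %d, p = %.4g\n  evenness = %.3f (1 = uniform), N = %d\n",
    x$statistic, x$df, x$p.value, x$evenness, as.integer(x$total)))
  invisible(x)
}
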