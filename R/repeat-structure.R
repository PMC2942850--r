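#' Detect identical direct-repeat families on a circular genome
#'
#' Finds maximal exact repeat families (k copies, k >= 2, direct orientation)
#' of at least `min_length` nt.  A family's *core* is the longest run shared
#' identically by all of its copies; flanking sequence shared by only a subset
#' of copies (the "extensions") is absorbed into the family rather than
#' reported as separate hits, and can be quantified with
#' [compute_extensions()].  The sequence is scanned as doubled text so repeats
#' crossing the origin are found; hits are deduplicated modulo the genome
#' length and a family core never exceeds it.
#'
#' Maximality: no family can be extended left or right in *all* copies
#' simultaneously.  Families are reported longest-first, ties by leftmost
#' start.  Low-complexity units (Shannon entropy of the core below
#' `entropy_min` bits) are flagged and suppressed by default.
#'
#' @param genome a `circular_genome`, or a plain sequence string.
#' @param min_length minimum core length to report (>= 8).
#' @param low_complexity_filter drop families flagged low-complexity.
#' @param entropy_min entropy floor in bits (mononucleotide Shannon entropy of
#'   the core; a homopolymer has 0, random sequence about 2).
#' @return A list of `repeat_family` objects: `core_length`, `n_copies`,
#'   `copies` (data frame of 0-based half-open circular intervals, direct
#'   orientation), `low_complexity`, and empty extension slots.
#' @export
find_repeat_families <- function(genome, min_length = 50L,
                                 low_complexity_filter = TRUE,
                                 entropy_min = 1.0) {
  seq <- if (inherits(genome, "circular_genome")) genome$seq else as.character(genome)
  min_length <- as.integer(min_length)
  if (min_length < 8L) stop_mitodyn("min_length must be >= 8")
  L <- nchar(seq)
  if (L < min_length) return(list())
  k <- min_length
  doubled <- paste0(seq, substr(seq, 1L, k - 1L))
  w <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
  idx <- match(w, w)
  tab <- tabulate(idx, nbins = L)
  dup_rep <- which(tab >= 2L & seq_len(L) == idx)   # one representative per group
  if (length(dup_rep) == 0L) return(list())

  # one record per duplicated k-mer content: anchor (min position) and shape
  pos_by_group <- split(seq_len(L), idx)
  groups <- pos_by_group[as.character(dup_rep)]
  anchors <- vapply(groups, `[`, 1L, i = 1L)
  shapes <- vapply(groups, function(p) paste(p - p[1L], collapse = ","), "")

  # merge runs of consecutive anchors with identical occurrence shape:
  # each run is one maximal repeat block
  ord <- order(shapes, anchors)
  blocks <- list()
  run_start <- 1L
  for (i in seq_along(ord)) {
    nxt_same <- i < length(ord) &&
      shapes[ord[i + 1L]] == shapes[ord[i]] &&
      anchors[ord[i + 1L]] == anchors[ord[i]] + 1L
    if (!nxt_same) {
      first <- ord[run_start]
      run_len <- i - run_start + 1L
      len <- min(k + run_len - 1L, L)
      blocks[[length(blocks) + 1L]] <- list(
        starts = groups[[first]] - 1L,        # 0-based
        length = len,
        degenerate = k + run_len - 1L > L)
      run_start <- i + 1L
    }
  }

  # absorb blocks fully explained by a family (extension material): block B
  # belongs to family A when every occurrence of B overlaps A's accumulated
  # territory (core copies plus already-absorbed extension blocks).  Blocks
  # are visited by copy number descending so extension shells absorb outward
  # from the core.
  ordb <- order(-vapply(blocks, function(b) length(b$starts), 1L),
                -vapply(blocks, `[[`, 1L, "length"),
                vapply(blocks, function(b) min(b$starts), 1L))
  blocks <- blocks[ordb]
  fams <- list()
  for (b in blocks) {
    b_iv <- cbind(b$starts, b$starts + b$length)
    absorbed <- FALSE
    for (fi in seq_along(fams)) {
      terr <- fams[[fi]]$territory
      ov <- vapply(seq_len(nrow(b_iv)), function(r)
        any(vapply(seq_len(nrow(terr)), function(ti)
          circ_intervals_overlap(b_iv[r, 1L], b_iv[r, 2L],
                                 terr[ti, 1L], terr[ti, 2L], L), TRUE)), TRUE)
      if (all(ov)) {
        fams[[fi]]$territory <- rbind(terr, b_iv)
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      b$territory <- b_iv
      fams[[length(fams) + 1L]] <- b
    }
  }

  out <- lapply(fams, function(f) {
    core <- circ_substr(seq, f$starts[1L], f$starts[1L] + f$length)
    ent <- seq_entropy(core)
    structure(list(
      core_length = f$length,
      n_copies = length(f$starts),
      copies = data.frame(copy = seq_along(f$starts), start = f$starts,
                          end = f$starts + f$length,
                          orientation = "direct", stringsAsFactors = FALSE),
      core_seq = core,
      low_complexity = ent < entropy_min || isTRUE(f$degenerate),
      entropy = ent,
      genome_length = L,
      left_extension = NULL, right_extension = NULL
    ), class = "repeat_family")
  })
  if (low_complexity_filter)
    out <- Filter(function(f) !f$low_complexity, out)
  ordf <- order(-vapply(out, `[[`, 1L, "core_length"),
                vapply(out, function(f) min(f$copies$start), 1L))
  out[ordf]
}

# interval overlap on a circle, 0-based half-open with end possibly > L
circ_intervals_overlap <- function(s1, e1, s2, e2, L) {
  d <- (s2 - s1) %% L
  if (d < (e1 - s1)) return(TRUE)
  d2 <- (s1 - s2) %% L
  d2 < (e2 - s2)
}

seq_entropy <- function(x) {
  counts <- table(strsplit(x, "")[[1]])
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' @export
print.repeat_family <- function(x, ...) {
  cat(sprintf("<repeat_family> %d identical copies of %d bp (direct)%s\n",
              x$n_copies, x$core_length,
              if (isTRUE(x$low_complexity)) " [low-complexity]" else ""))
  if (!is.null(x$left_extension))
    cat(sprintf("  extensions computed: left max %d, right max %d\n",
                max(x$left_extension, na.rm = TRUE),
                max(x$right_extension, na.rm = TRUE)))
  invisible(x)
}

#' Compute the shared flanking-extension structure of a repeat family
#'
#' For every pair of copies (i, j), `left_extension[i, j]` is the length of
#' the longest common suffix of the sequences immediately 5' of copies i and j
#' (the shared left-flank extension) and `right_extension[i, j]` the longest
#' common prefix of their 3' flanks.  Flank comparisons are bounded so they
#' never cross into another copy of the family.  If *all* copies share a
#' non-empty extension on one side, that sequence belongs to the core by
#' maximality: the family is re-extended (with a warning) and the matrices
#' recomputed.
#'
#' @param genome a `circular_genome` or sequence string.
#' @param family a `repeat_family` whose copies are verified identical.
#' @return The family with symmetric `left_extension` / `right_extension`
#'   matrices filled (diagonal `NA`).
#' @export
compute_extensions <- function(genome, family) {
  seq <- if (inherits(genome, "circular_genome")) genome$seq else as.character(genome)
  stopifnot(inherits(family, "repeat_family"))
  L <- nchar(seq)
  n <- family$n_copies
  starts <- family$copies$start
  ends <- family$copies$end
  len <- family$core_length

  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (circ_intervals_overlap(starts[i], ends[i], starts[j], ends[j], L))
        stop_mitodyn("repeat copies overlap; extensions are undefined")
  }
  seqs <- vapply(seq_len(n), function(i) circ_substr(seq, starts[i] %% L, starts[i] %% L + len), "")
  if (length(unique(seqs)) != 1L)
    stop_mitodyn("family copies are not identical")

  repeat {
    # bound flanks by the nearest neighbouring copy
    flank_left <- character(n); flank_right <- character(n)
    for (i in seq_len(n)) {
      d_prev <- min(vapply(seq_len(n)[-i], function(j)
        circ_dist(ends[j] %% L, starts[i] %% L, L), 1))
      d_next <- min(vapply(seq_len(n)[-i], function(j)
        circ_dist(ends[i] %% L, starts[j] %% L, L), 1))
      if (n == 1L) { d_prev <- d_next <- L - len }
      s <- (starts[i] - d_prev) %% L
      flank_left[i] <- circ_substr(seq, s, s + d_prev)
      flank_right[i] <- circ_substr(seq, ends[i] %% L, ends[i] %% L + d_next)
    }
    lmat <- matrix(NA_integer_, n, n); rmat <- matrix(NA_integer_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      lmat[i, j] <- lcs_length(flank_left[i], flank_left[j])
      rmat[i, j] <- lcp_length(flank_right[i], flank_right[j])
    }
    if (n < 2L) break
    shared_l <- min(lmat[upper.tri(lmat) | lower.tri(lmat)])
    shared_r <- min(rmat[upper.tri(rmat) | lower.tri(rmat)])
    if (shared_l == 0L && shared_r == 0L) break
    warning("flank sequence shared by all copies; re-extending the family core by ",
            shared_l + shared_r, " nt", call. = FALSE)
    starts <- starts - shared_l
    ends <- ends + shared_r
    len <- len + shared_l + shared_r
  }
  family$core_length <- len
  family$copies$start <- starts %% L
  family$copies$end <- starts %% L + len
  family$core_seq <- circ_substr(seq, starts[1L] %% L, starts[1L] %% L + len)
  family$left_extension <- lmat
  family$right_extension <- rmat
  family
}

#' Construct a repeat family from generator ground truth
#'
#' Convenience constructor used when the planted structure is known, e.g. to
#' feed [support_from_read_pairs()] or [compute_extensions()] without running
#' detection.
#'
#' @param truth a `genome_truth` from [make_genome()].
#' @return A `repeat_family`.
#' @export
family_from_truth <- function(truth) {
  stopifnot(inherits(truth, "genome_truth"))
  structure(list(
    core_length = truth$core_length,
    n_copies = truth$n_repeats,
    copies = data.frame(copy = seq_len(truth$n_repeats),
                        start = truth$repeat_copy_intervals$start,
                        end = truth$repeat_copy_intervals$end,
                        orientation = "direct", stringsAsFactors = FALSE),
    core_seq = NULL, low_complexity = FALSE, entropy = NA_real_,
    genome_length = truth$genome_length,
    left_extension = NULL, right_extension = NULL
  ), class = "repeat_family")
}
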