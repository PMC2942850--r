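#' Build the equilibrium pool of repeat-junction molecules
#'
#' For an n-copy recombining direct repeat there are n^2 ordered (left flank,
#' right flank) pairs.  This constructs one linear junction molecule per pair:
#' the `span` nt immediately 5' of core copy `i`, the core, and the `span` nt
#' immediately 3' of core copy `j`.  Uniform weights encode recombinational
#' equilibrium — the state in which all alternative flanking arrangements occur
#' at (approximately) equal stoichiometry.
#'
#' @param genome a `circular_genome` from [make_genome()].
#' @param truth the matching `genome_truth`.
#' @param weights sampling weight per flanking pair: an n x n matrix
#'   (rows = left flank id, cols = right flank id) or a length-n^2 vector in
#'   row-major order; default uniform.  Must be non-negative with positive sum.
#' @param span nt of flanking sequence retained on each side of the core;
#'   default `min(min(singlecopy_lengths) - 100, 2750)` — subclone-sized
#'   junction molecules just longer than the largest insert, never running
#'   into a neighbouring core copy.
#' @return A `molecule_pool`: data frame (`left_id`, `right_id`, `weight`,
#'   `length`, `seq`) with the genome and truth attached as attributes.
#' @export
make_equilibrium_molecules <- function(genome, truth, weights = NULL, span = NULL) {
  stopifnot(inherits(genome, "circular_genome"), inherits(truth, "genome_truth"))
  n <- truth$n_repeats
  L <- genome$length
  gaps <- truth$singlecopy_intervals$end - truth$singlecopy_intervals$start
  if (is.null(span)) span <- min(min(gaps) - 100L, 2750L)
  span <- as.integer(span)
  if (span < 1L || span > min(gaps))
    stop_mitodyn("span must be in [1, min single-copy length] so molecules do ",
                 "not cross a neighbouring repeat copy")
  if (is.null(weights)) weights <- matrix(1, n, n)
  if (is.matrix(weights)) {
    stopifnot(nrow(weights) == n, ncol(weights) == n)
    w <- as.vector(t(weights))          # row-major: (i, j) pairs
  } else {
    if (length(weights) != n * n)
      stop_mitodyn("weights must cover all n^2 flanking pairs")
    w <- as.numeric(weights)
  }
  if (any(w < 0)) stop_mitodyn("weights must be non-negative")
  if (sum(w) <= 0) stop_mitodyn("total weight is zero")

  P <- truth$repeat_copy_intervals$start
  core_end <- truth$repeat_copy_intervals$end
  core_seq <- circ_substr(genome$seq, P[1L], core_end[1L])
  left_flank <- vapply(seq_len(n), function(i)
    circ_substr(genome$seq, (P[i] - span) %% L, (P[i] - span) %% L + span), "")
  right_flank <- vapply(seq_len(n), function(j)
    circ_substr(genome$seq, core_end[j] %% L, core_end[j] %% L + span), "")

  grid <- expand.grid(right_id = seq_len(n), left_id = seq_len(n))[, 2:1]
  seqs <- paste0(left_flank[grid$left_id], core_seq, right_flank[grid$right_id])
  pool <- data.frame(left_id = grid$left_id, right_id = grid$right_id,
                     weight = w, length = nchar(seqs), seq = seqs,
                     stringsAsFactors = FALSE)
  attr(pool, "genome") <- genome
  attr(pool, "truth") <- truth
  attr(pool, "span") <- span
  class(pool) <- c("molecule_pool", "data.frame")
  pool
}

#' @export
print.molecule_pool <- function(x, ...) {
  cat(sprintf("<molecule_pool> %d junction molecules (%d flanks), span %d nt, %s weights\n",
              nrow(x), length(unique(x$left_id)), attr(x, "span"),
              if (length(unique(x$weight)) == 1L) "uniform" else "non-uniform"))
  invisible(x)
}

#' Simulate Sanger-style paired-end subclone reads from a molecule pool
#'
#' Read pairs are drawn from molecules proportionally to their weights.
#' Inserts are uniform over `insert_range`; the forward read is the first
#' `read_length` nt of the insert and the reverse read is the reverse
#' complement of its last `read_length` nt.  Reads are error-free by default.
#' Coverage is *genome* sequence coverage — the depth a shotgun library of
#' this size would give the underlying genome — so the pair count is
#' `round(coverage * genome_length / mean_insert)`; junction molecules of a
#' recombining repeat are correspondingly sparsely sampled at low coverage,
#' exactly as subclones of a real library are.
#'
#' @param pool a `molecule_pool`.
#' @param coverage fold genome sequence coverage (0 gives no reads).
#' @param insert_range c(min, max) insert length in nt.
#' @param read_length read length in nt (must be < min insert).
#' @param seed integer seed.
#' @param error_rate optional per-base uniform substitution error rate.
#' @return A `read_pairs` data frame: `read1`, `read2` (reverse-complemented),
#'   ground-truth `molecule` (pool row), `left_id`, `right_id`, `start`
#'   (0-based on the molecule) and `insert`.
#' @export
make_read_pairs <- function(pool, coverage = 7, insert_range = c(4000L, 6500L),
                            read_length = 700L, seed = 1L, error_rate = 0) {
  stopifnot(inherits(pool, "molecule_pool"))
  insert_range <- as.integer(insert_range)
  read_length <- as.integer(read_length)
  if (insert_range[2L] < insert_range[1L])
    stop_mitodyn("insert_range must be (min, max) with max >= min")
  if (read_length >= insert_range[1L])
    stop_mitodyn("read_length must be smaller than the minimum insert")
  if (any(pool$length < insert_range[2L]))
    stop_mitodyn("some molecules are shorter than the maximum insert; ",
                 "increase the molecule span")
  mean_insert <- mean(insert_range)
  genome_length <- attr(pool, "genome")$length %||% sum(pool$length)
  n_pairs <- round(coverage * genome_length / mean_insert)
  empty <- data.frame(read1 = character(0), read2 = character(0),
                      molecule = integer(0), left_id = integer(0),
                      right_id = integer(0), start = integer(0),
                      insert = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("read_pairs", "data.frame")
  if (n_pairs < 1L) return(empty)
  with_seed(seed, {
    mol <- sample.int(nrow(pool), n_pairs, replace = TRUE, prob = pool$weight)
    ins <- sample.int(insert_range[2L] - insert_range[1L] + 1L, n_pairs,
                      replace = TRUE) + insert_range[1L] - 1L
    maxs <- pool$length[mol] - ins + 1L
    s <- floor(stats::runif(n_pairs) * maxs) + 1L   # 1-based start
    read1 <- substr(pool$seq[mol], s, s + read_length - 1L)
    read2 <- revcomp_vec(substr(pool$seq[mol], s + ins - read_length, s + ins - 1L))
    if (error_rate > 0) {
      read1 <- sprinkle_errors(read1, error_rate)
      read2 <- sprinkle_errors(read2, error_rate)
    }
    out <- data.frame(read1 = read1, read2 = read2, molecule = mol,
                      left_id = pool$left_id[mol], right_id = pool$right_id[mol],
                      start = s - 1L, insert = ins, stringsAsFactors = FALSE)
    class(out) <- c("read_pairs", "data.frame")
    out
  })
}

sprinkle_errors <- function(reads, rate) {
  vapply(reads, function(r) {
    hits <- which(stats::runif(nchar(r)) < rate)
    for (p in hits) {
      old <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
    r
  }, "", USE.NAMES = FALSE)
}
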