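#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

# Deterministic stream splitting: one top-level seed, one child stream per
# generator call.  Children stay below 2^31 - 1 so they are valid R seeds.
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) %% 2147483647) * 48271 + k * 16807) %% 2147483647L
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit.  `seed = NULL` uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Vectorised reverse complement for plain character vectors.
revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Length of the longest common prefix of two strings.
lcp_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Length of the longest common suffix of two strings.
lcs_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# --- circular coordinates -------------------------------------------------
# All intervals are 0-based half-open [start, end); on a circular sequence of
# length L the canonical unwrapping has start in [0, L) while end may exceed L.

# Extract [start, end) from a circular sequence given as a plain string.
circ_substr <- function(seq, start, end) {
  L <- nchar(seq)
  stopifnot(start >= 0, end >= start, end - start <= L)
  if (end <= L) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
}

# Does circular interval [s1,e1) overlap [s2,e2) on a circle of length L?
circ_overlaps <- function(s1, e1, s2, e2, L) {
  span1 <- seq.int(s1, e1 - 1L) %% L
  span2 <- seq.int(s2, e2 - 1L) %% L
  length(intersect(span1, span2)) > 0L
}

# Circular distance from a to b walking forward (0 <= d < L).
circ_dist <- function(a, b, L) (b - a) %% L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mitodyn <- function(...) stop(..., call. = FALSE)
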