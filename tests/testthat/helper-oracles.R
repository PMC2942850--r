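# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package internals they check.

# --- repeats: brute-force longest duplicated substring on a circle ---------
# Returns list(length, positions) of the longest substring occurring >= 2
# times (positions 0-based, deduplicated modulo L), by direct scan over
# window lengths (binary search on k; duplicate detection via substring
# comparison only).
oracle_longest_repeat <- function(seq, min_length = 8L) {
  L <- nchar(seq)
  doubled <- paste0(seq, seq)
  dup_at <- function(k) {
    if (k > L) return(NULL)
    w <- substring(doubled, seq_len(L), seq_len(L) + k - 1L)
    d <- duplicated(w) | duplicated(w, fromLast = TRUE)
    if (!any(d)) return(NULL)
    split(which(d) - 1L, w[d])
  }
  lo <- min_length; hi <- L
  if (is.null(dup_at(lo))) return(NULL)
  while (lo < hi) {                      # largest k with a duplicate
    mid <- (lo + hi + 1L) %/% 2L
    if (!is.null(dup_at(mid))) lo <- mid else hi <- mid - 1L
  }
  groups <- dup_at(lo)
  sizes <- lengths(groups)
  best <- groups[[which.max(sizes)]]
  list(length = lo, positions = sort(best))
}

# --- conformations: explicit enumeration with rotation dedup ---------------
oracle_count_cyclic_orders <- function(n, k = n) {
  # distinct cyclic sequences of a k-subset of 1..n (orientation fixed)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  canon <- function(p) {
    rots <- vapply(seq_along(p), function(r)
      paste(c(p[r:length(p)], p[seq_len(r - 1L)]), collapse = ","), "")
    min(rots)
  }
  subsets <- utils::combn(n, k, simplify = FALSE)
  total <- 0L
  for (s in subsets)
    total <- total + length(unique(vapply(perms(s), canon, "")))
  total
}

# --- RNA energy: independent recursive loop-decomposition evaluator --------
oracle_energy <- function(sequence, dotbracket, params, lenient_stack = 0) {
  v <- strsplit(toupper(gsub("T", "U", sequence)), "")[[1L]]
  ch <- strsplit(dotbracket, "")[[1L]]
  n <- length(ch)
  pt <- integer(n); stack <- integer(0L)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") { j <- stack[length(stack)]
      stack <- stack[-length(stack)]; pt[i] <- j; pt[j] <- i }
  }
  ptype <- function(i, j) {
    key <- paste0(v[i], v[j])
    if (key %in% rownames(params$stack)) key else NA_character_
  }
  stk <- function(p, q) {
    if (is.na(p) || is.na(q)) lenient_stack else params$stack[p, q]
  }
  lp <- function(tab, size) {
    sizes <- as.integer(names(tab))
    if (size <= max(sizes)) unname(tab[as.character(size)])
    else unname(tab[as.character(max(sizes))]) + params$lxc * log(size / max(sizes))
  }
  eval_pair <- function(i, j) {
    kids <- list(); k <- i + 1L
    while (k < j) {
      if (pt[k] > k) { kids[[length(kids) + 1L]] <- c(k, pt[k]); k <- pt[k] + 1L }
      else k <- k + 1L
    }
    if (length(kids) == 0L) return(lp(params$hairpin, j - i - 1L))
    inner <- sum(vapply(kids, function(kd) eval_pair(kd[1L], kd[2L]), 0))
    if (length(kids) == 1L) {
      a <- kids[[1L]][1L]; b <- kids[[1L]][2L]
      l <- a - i - 1L; r <- j - b - 1L
      term <- if (l == 0L && r == 0L) stk(ptype(i, j), ptype(a, b))
      else if (l == 0L || r == 0L) lp(params$bulge, l + r)
      else lp(params$internal, l + r)
      return(term + inner)
    }
    unp <- (j - i - 1L) - sum(vapply(kids, function(kd) kd[2L] - kd[1L] + 1L, 0L))
    params$multiloop[["offset"]] + params$multiloop[["branch"]] * (length(kids) + 1L) +
      params$multiloop[["unpaired"]] * unp + inner
  }
  total <- 0; k <- 1L
  while (k <= n) {
    if (pt[k] > k) { total <- total + eval_pair(k, pt[k]); k <- pt[k] + 1L }
    else k <- k + 1L
  }
  total
}

# --- gene conversion: exhaustive maximal-segment oracle --------------------
# All maximal scoring subsequences by recursive extraction of the maximum-
# score interval (ties: largest start, then smallest end), O(m^2).
oracle_fragments <- function(x) {
  rec <- function(lo, hi) {
    if (lo > hi) return(NULL)
    best <- 0; bi <- NA_integer_; bj <- NA_integer_
    for (i in lo:hi) {
      s <- 0
      for (j in i:hi) {
        s <- s + x[j]
        if (s > best) { best <- s; bi <- i; bj <- j }
        else if (s == best && best > 0 &&
                 (i > bi || (i == bi && j < bj))) { bi <- i; bj <- j }
      }
    }
    if (best <= 0) return(NULL)
    rbind(rec(lo, bi - 1L), c(bi, bj, best), rec(bj + 1L, hi))
  }
  out <- rec(1L, length(x))
  if (!is.null(out)) out <- out[order(out[, 1L]), , drop = FALSE]
  out
}

# small helper: a genome spec scaled for fast repeated generation
small_genome_spec <- function(seed, n = 6L, core = 1362L) {
  genome_spec(n_repeats = n, core_length = core,
              extension_left = c(0L, 12L, 30L, 60L, 120L, 200L)[seq_len(n)],
              extension_right = c(0L, 15L, 40L, 80L, 150L, 250L)[seq_len(n)],
              singlecopy_lengths = rep(600L, n),
              seed = seed)
}
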