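# Internal helpers shared across modules.

#' Hamming distance between equal-length strings
#'
#' Vectorised over pairs: `a` and `b` are recycled to a common length and
#' compared element-wise. Both strings of a pair must have equal nchar.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of per-pair mismatch counts.
#' @examples
#' hamming("ACT", c("ACT", "AGT", "TGA"))
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    abort("hamming(): strings of a pair must have equal length")
  }
  vapply(seq_len(n), function(i) {
    sum(charToRaw(a[i]) != charToRaw(b[i]))
  }, integer(1))
}

# Minimum Hamming distance of each candidate to a set of reference strings,
# with the lexicographically smallest reference winning distance ties.
# Returns list(n = integer, template = character).
nearest_template <- function(candidates, templates) {
  templates <- sort(templates)
  d <- vapply(templates, function(t) hamming(candidates, t),
              integer(length(candidates)))
  if (length(candidates) == 1L) d <- matrix(d, nrow = 1L)
  idx <- apply(d, 1L, which.min)  # first (lexicographically smallest) on ties
  list(
    n = d[cbind(seq_along(candidates), idx)],
    template = templates[idx]
  )
}

# Symmetric-capable Dirichlet draw: one frequency vector of length k.
rdirichlet1 <- function(alpha, k = length(alpha)) {
  alpha <- rep_len(alpha, k)
  g <- rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- rgamma(k, shape = alpha)  # degenerate guard
  g / sum(g)
}

#' Locate low-complexity tracts in a sequence
#'
#' Finds homopolymer runs of at least `min_homopolymer` bases and contiguous
#' tandem repeats of a 2-6 bp motif repeated at least `min_copies` times.
#' These are the tracts the screener rejects and the extractor masks around,
#' because they are prone to amplification, sequencing and alignment errors.
#'
#' @param seq A single DNA sequence string.
#' @param min_homopolymer Minimum homopolymer run length (default 6).
#' @param min_unit,max_unit Tandem motif length bounds (default 2-6 bp).
#' @param min_copies Minimum contiguous motif copies (default 3).
#' @return A tibble with columns `start`, `end` (1-based, inclusive) and
#'   `type` (`"homopolymer"` or `"tandem"`); zero rows if clean.
#' @examples
#' repeat_tracts("ACGTAAAAAAACGACACACACGT")
#' @export
repeat_tracts <- function(seq, min_homopolymer = 6, min_unit = 2,
                          max_unit = 6, min_copies = 3) {
  stopifnot(length(seq) == 1L)
  out <- list()
  pat_h <- sprintf("([ACGTN])\\1{%d,}", min_homopolymer - 1L)
  m <- gregexpr(pat_h, seq, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    out[[length(out) + 1L]] <- tibble(
      start = as.integer(m),
      end = as.integer(m) + attr(m, "match.length") - 1L,
      type = "homopolymer"
    )
  }
  pat_t <- sprintf("([ACGTN]{%d,%d})\\1{%d,}", min_unit, max_unit,
                   min_copies - 1L)
  m <- gregexpr(pat_t, seq, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    out[[length(out) + 1L]] <- tibble(
      start = as.integer(m),
      end = as.integer(m) + attr(m, "match.length") - 1L,
      type = "tandem"
    )
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), type = character()))
  }
  arrange(bind_rows(out), .data$start)
}

# TRUE if the sequence contains any repeat tract.
has_repeat <- function(seq, ...) nrow(repeat_tracts(seq, ...)) > 0L

# Pool-adjacent-violators fit, constrained non-increasing, equal weights.
pava_nonincreasing <- function(y) {
  if (length(y) <= 1L) return(y)
  f <- isoreg(seq_along(y), -y)
  -f$yf
}

# Largest-remainder (Hamilton) integer allocation of n among weights.
allocate_counts <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Lightweight classed-tibble constructor.
msmix_tbl <- function(x, subclass) {
  class(x) <- c(subclass, class(tibble()))
  x
}
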