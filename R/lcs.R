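# Phase 1: secondary-structure-string comparison by
# longest-common-subsequence dynamic programming, traceback for the
# initial alignment, and the pass/fail length filter.

sse_to_int <- function(s) {
  if (is.character(s) && length(s) == 1L) utf8ToInt(s) else as.integer(s)
}

#' LCS dynamic-programming matrix of two SSE strings
#'
#' Fills the (m+1) x (n+1) scoring matrix: borders 0, diagonal + 1 on a
#' character match, max(up, left) otherwise.  `S[m+1, n+1]` is the LCS
#' length of the full strings.
#'
#' @param a,b secondary-structure strings (any characters are accepted;
#'   the alignment alphabet is `{H, E, C, O}`).
#' @return Integer matrix of dimension `(nchar(a)+1) x (nchar(b)+1)`.
#' @export
lcs_matrix <- function(a, b) {
  cpp_lcs_fill(sse_to_int(a), sse_to_int(b))
}

#' LCS length only
#'
#' Linear-memory variant used when screening many database entries,
#' where the full matrix (needed only for traceback) is not wanted.
#'
#' @inheritParams lcs_matrix
#' @return Integer LCS length.
#' @export
lcs_length <- function(a, b) {
  cpp_lcs_length(sse_to_int(a), sse_to_int(b))
}

#' Traceback of the LCS matrix: the initial alignment
#'
#' Recovers one optimal common subsequence as ordered index pairs.
#' Deterministic tie-breaking: a character match is always taken
#' diagonally; on a mismatch the move goes up (drop a character of `a`)
#' only when that cell is strictly larger, otherwise left.
#'
#' @param S matrix from [lcs_matrix()] computed on `a`, `b`.
#' @inheritParams lcs_matrix
#' @return List with `pairs` (k x 2 integer matrix of 1-based positions
#'   into `a` and `b`, strictly increasing in both columns) and
#'   `lcs_length` (= `S[m+1, n+1]`).
#' @export
lcs_traceback <- function(S, a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  m <- length(av); n <- length(bv)
  if (!all(dim(S) == c(m + 1L, n + 1L)))
    stop("matrix dimensions do not match the strings")
  i <- m; j <- n
  pi <- integer(0); pj <- integer(0)
  while (i > 0L && j > 0L) {
    if (av[i] == bv[j]) {
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1L; j <- j - 1L
    } else if (S[i, j + 1L] > S[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(pairs = cbind(a = pi, b = pj), lcs_length = S[m + 1L, n + 1L])
}

#' Phase-1 filter decision
#'
#' A pair passes when the LCS length strictly exceeds
#' `min(m, n) * factor`.  The threshold is kept as a float (no
#' rounding) and the comparison is strict.
#'
#' @param lcs_len LCS length of the two SSE strings.
#' @param m,n string lengths (>= 1).
#' @param factor threshold fraction in `(0, 1]`; default 0.7.
#' @return Logical scalar.
#' @examples
#' passes_filter(71, 200, 100)   # threshold 70: pass
#' passes_filter(70, 200, 100)   # strict: fail
#' @export
passes_filter <- function(lcs_len, m, n, factor = 0.7) {
  if (m < 1L || n < 1L) stop("string lengths must be >= 1")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop("factor must lie in (0, 1]")
  lcs_len > min(m, n) * factor
}
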