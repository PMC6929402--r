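# Independent oracles used to pin down expected values.  These stay
# deliberately naive: brute-force enumeration, never the package's own
# dynamic programming.

is_subsequence <- function(x, y) {
  j <- 1L; n <- length(y)
  for (ch in x) {
    while (j <= n && y[j] != ch) j <- j + 1L
    if (j > n) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

# Exhaustive LCS: enumerate every subsequence of the shorter string,
# longest first, and return the length of the first that is also a
# subsequence of the other string.
oracle_lcs <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) > length(bv)) { tmp <- av; av <- bv; bv <- tmp }
  m <- length(av)
  if (m == 0L) return(0L)
  masks <- 0:(2^m - 1L)
  bits <- matrix(FALSE, length(masks), m)
  for (k in seq_len(m))
    bits[, k] <- bitwAnd(masks, bitwShiftL(1L, k - 1L)) > 0L
  lens <- rowSums(bits)
  for (r in order(-lens)) {
    if (is_subsequence(av[bits[r, ]], bv)) return(as.integer(lens[r]))
  }
  0L
}

# Exhaustive max over all monotone alignment paths of the residue-level
# objective: paths reaching (m,n) by up (+g), left (+g) and diagonal
# (+term) moves; per the recurrence, any border cell (i=0 or j=0) is a
# free starting point.  Exponential; for tiny matrices only.
oracle_dp_max <- function(term, g) {
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    max(rec(i - 1L, j) + g,
        rec(i, j - 1L) + g,
        rec(i - 1L, j - 1L) + term[i, j])
  }
  rec(nrow(term), ncol(term))
}

# Enumerate ALL optimal LCS pair lists (for checking that a traceback
# result is a member of the optimal set).
oracle_all_lcs_paths <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best_len <- oracle_lcs(a, b)
  paths <- list()
  rec <- function(i, j, acc) {
    if (length(acc) == best_len) {
      paths[[length(paths) + 1L]] <<- do.call(rbind, acc)
      return()
    }
    if (i > length(av) || j > length(bv)) return()
    # prune: remaining length cannot reach best_len
    if (length(acc) + min(length(av) - i + 1L, length(bv) - j + 1L) < best_len)
      return()
    for (ii in i:length(av)) for (jj in j:length(bv)) {
      if (av[ii] == bv[jj]) rec(ii + 1L, jj + 1L, c(acc, list(c(ii, jj))))
    }
  }
  rec(1L, 1L, list())
  unique(paths)
}

with_seed_for_test <- pdbalign:::with_seed

pair_dist_for_test <- function(sup, A, B) {
  sqrt(rowSums((apply_superposition(sup, A) - B)^2))
}

random_sse_string <- function(n) {
  paste(sample(c("H", "E", "C", "O"), n, replace = TRUE), collapse = "")
}
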