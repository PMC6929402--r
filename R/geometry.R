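# Rigid-body superposition and similarity metrics.

#' Kabsch least-squares superposition
#'
#' Closed-form SVD solution for the proper rotation and translation that
#' minimise the sum of squared distances when `moving` is mapped onto
#' `fixed`.  A reflection in the SVD solution is corrected by flipping
#' the sign of the smallest singular direction, so the returned rotation
#' always has determinant +1.
#'
#' @param moving,fixed n x 3 coordinate matrices (or `ca_chain` objects)
#'   with rows in correspondence; n must be at least 3.
#' @return An object of class `superposition`: list with `rotation`
#'   (3 x 3, det +1) and `translation` (length 3), representing the map
#'   `x -> R x + t`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' s <- kabsch(a, a)        # identity transform
#' @export
kabsch <- function(moving, fixed) {
  P <- as_xyz(moving); Q <- as_xyz(fixed)
  if (nrow(P) != nrow(Q))
    stop("coordinate sets must have equal length")
  if (nrow(P) < 3L)
    stop("superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)                 # 3 x 3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cq - R %*% cp)
  structure(list(rotation = R, translation = t), class = "superposition")
}

#' Apply a rigid superposition to coordinates
#'
#' @param sup a `superposition` from [kabsch()].
#' @param xyz n x 3 coordinate matrix (or `ca_chain`).
#' @return Transformed n x 3 matrix `xyz %*% t(R) + t`.
#' @export
apply_superposition <- function(sup, xyz) {
  m <- as_xyz(xyz)
  sweep(m %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition>\nrotation:\n")
  print(round(x$rotation, 4))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

# Per-pair distances between already-corresponding rows of A (moved by
# sup) and B.
pair_distances <- function(sup, xyzA, xyzB) {
  a <- apply_superposition(sup, as_xyz(xyzA))
  sqrt(rowSums((a - as_xyz(xyzB))^2))
}

#' Root-mean-square deviation over aligned pairs
#'
#' `sqrt(mean(d^2))` over the per-pair distances of an alignment under a
#' rigid superposition.
#'
#' @param d numeric vector of per-pair distances (Angstrom), length >= 1.
#' @return RMSD in Angstrom.
#' @examples
#' rmsd(c(3, 4))   # sqrt((9 + 16)/2)
#' @export
rmsd <- function(d) {
  if (length(d) == 0L)
    stop("RMSD of an empty pair set is undefined")
  sqrt(mean(d^2))
}

#' TM-score distance scale d0
#'
#' `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8` Angstrom, clamped below at
#' 0.5 A so the score stays well defined for short chains and fragments
#' (for L <= 21 the formula goes nonpositive).
#'
#' @param L normalisation length (residues), >= 1.
#' @return d0 in Angstrom; vectorised over `L`.
#' @export
d0 <- function(L) {
  x <- L - 15
  raw <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' TM-score of an alignment under a fixed superposition
#'
#' `(1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)`, where the sum runs over
#' the aligned pairs.  Unaligned residues of the normalising structure
#' contribute zero, so coverage and accuracy are both rewarded.  The
#' maximisation over superpositions is done by [tm_score_optimal()].
#'
#' @param d per-pair distances (Angstrom) under the superposition; an
#'   empty vector scores 0.
#' @param l_norm normalisation length (>= length(d)).
#' @param d0_len length used inside [d0()]; defaults to `l_norm`.
#' @return Score in `[0, 1]`.
#' @export
tm_score <- function(d, l_norm, d0_len = l_norm) {
  if (length(d) == 0L) return(0)
  stopifnot(l_norm >= 1)
  sum(1 / (1 + (d / d0(d0_len))^2)) / l_norm
}

#' TM-score maximised over superpositions
#'
#' Realises the max operator of the TM-score by seeded iterative
#' distance-cutoff refinement.  Seed superpositions are the Kabsch fit
#' on all pairs plus fits on contiguous pair windows (halves and
#' quarters anchored along the alignment, as fragment-based aligners
#' seed their search); from each seed the fit is repeated on the subset
#' of pairs closer than a cutoff (schedule 8, 7, 6, 5, 4.5, 4, 3.5 A
#' and finally d0), scoring every candidate superposition over ALL
#' pairs and keeping the best.  Each cutoff iterates until its pair
#' subset stabilises (at most 20 rounds).  Deterministic; the result is
#' never below the plain Kabsch score.
#'
#' @param xyzA,xyzB n x 3 matrices of corresponding coordinates
#'   (template and constant sides of the aligned pairs), n >= 3.
#' @param l_norm normalisation length.
#' @param d0_len length used for d0; defaults to `l_norm`.
#' @return List: `tm` (best score), `sup` (the superposition achieving
#'   it), `d` (per-pair distances under `sup`).
#' @export
tm_score_optimal <- function(xyzA, xyzB, l_norm, d0_len = l_norm) {
  A <- as_xyz(xyzA); B <- as_xyz(xyzB)
  n <- nrow(A)
  if (n < 3L)
    stop("TM-score optimisation needs at least 3 aligned pairs")
  score_sup <- function(sup) {
    d <- pair_distances(sup, A, B)
    list(tm = tm_score(d, l_norm, d0_len), sup = sup, d = d)
  }
  # deterministic seeds: all pairs, then contiguous windows of half and
  # quarter length anchored along the alignment
  seed_windows <- list(seq_len(n))
  for (w in unique(pmax(3L, c(n %/% 2L, n %/% 4L)))) {
    if (w >= n) next
    starts <- unique(pmax(1L, pmin(n - w + 1L,
                                   c(1L, (n - w) %/% 2L + 1L, n - w + 1L))))
    for (s in starts) seed_windows <- c(seed_windows, list(s:(s + w - 1L)))
  }
  best <- NULL
  cutoffs <- c(8, 7, 6, 5, 4.5, 4, 3.5, d0(d0_len))
  for (win in seed_windows) {
    cand <- score_sup(kabsch(A[win, , drop = FALSE], B[win, , drop = FALSE]))
    if (is.null(best) || cand$tm > best$tm) best <- cand
    start <- cand
    for (cut in cutoffs) {
      sel <- start$d < cut
      for (iter in seq_len(20L)) {
        if (sum(sel) < 3L) break
        cand <- score_sup(kabsch(A[sel, , drop = FALSE],
                                 B[sel, , drop = FALSE]))
        if (cand$tm > best$tm) best <- cand
        new_sel <- cand$d < cut
        if (identical(new_sel, sel)) break
        sel <- new_sel
      }
    }
  }
  best
}
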