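# Phase 2: fragment-based residue-level alignment.  The shorter chain
# (template) is threaded gaplessly along the longer one (constant); at
# each window a Kabsch fit seeds a distance-reward scoring matrix whose
# traceback gives an alignment, long gapless fragments re-seed one
# refined superposition, and the best-scoring window wins.  The whole
# procedure is repeated with the template split into 1, 2, 3, 5 and 8
# equal parts, and the part-group whose combined alignment reaches the
# highest TM-score is reported.

#' Pick template and constant chains
#'
#' The chain with fewer residues becomes the template (the structure
#' that is moved and split); the other is the constant.  On equal
#' lengths the first argument is the template.
#'
#' @param chain_a,chain_b `ca_chain` objects.
#' @return List with `template`, `constant` and `template_is_first`.
#' @export
choose_template <- function(chain_a, chain_b) {
  first <- length(chain_a) <= length(chain_b)
  list(template = if (first) chain_a else chain_b,
       constant = if (first) chain_b else chain_a,
       template_is_first = first)
}

#' Residue-level scoring matrix
#'
#' Fills the (L+1) x (W+1) matrix with borders 0 and recurrence
#' `max(up + g, left + g, diag + 1/(1 + d_ij^2/d0^2))`, where `d_ij` is
#' the distance between template residue i (under `sup`) and window
#' residue j, and d0 is evaluated at the full template length.
#'
#' @param template_xyz,window_xyz coordinate matrices (or `ca_chain`s).
#' @param sup superposition applied to the template side.
#' @param g gap penalty, added on every gap move exactly as given
#'   (default 3e-6; 0.08 suits structurally analogous pairs better).
#' @param d0_len length at which [d0()] is evaluated; defaults to the
#'   template length.
#' @return List of class `score_matrix`: `M` (the DP matrix), `term`
#'   (match rewards), `g`.
#' @export
score_matrix <- function(template_xyz, window_xyz, sup, g = 3e-6,
                         d0_len = nrow(as_xyz(template_xyz))) {
  t_xyz <- apply_superposition(sup, template_xyz)
  w_xyz <- as_xyz(window_xyz)
  # squared cross-distances, template rows x window columns
  d2 <- outer(rowSums(t_xyz^2), rowSums(w_xyz^2), "+") -
    2 * tcrossprod(t_xyz, w_xyz)
  d2[d2 < 0] <- 0
  term <- 1 / (1 + d2 / d0(d0_len)^2)
  structure(list(M = cpp_fill_m(term, g), term = term, g = g),
            class = "score_matrix")
}

#' Traceback of the residue-level matrix
#'
#' Global traceback from the bottom-right corner; gaps permitted;
#' deterministic tie-break diagonal > up > left.
#'
#' @param sm a `score_matrix` from [score_matrix()].
#' @return k x 2 integer matrix of 1-based (template, window) pairs,
#'   strictly increasing in both columns.
#' @export
dp_traceback <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  p <- cpp_traceback_m(sm$M, sm$term, sm$g)
  colnames(p) <- c("template", "window")
  p
}

#' Gapless fragments of an alignment
#'
#' Maximal runs of aligned pairs in which both indices advance by
#' exactly one, kept when at least `min_len` pairs long.  These runs
#' seed the refined superposition.
#'
#' @param pairs k x 2 integer matrix, strictly increasing in both
#'   columns.
#' @param min_len minimum run length (default 10).
#' @return List of integer index vectors into the rows of `pairs`.
#' @export
collect_fragments <- function(pairs, min_len = 10L) {
  k <- nrow(pairs)
  if (k == 0L) return(list())
  step <- c(FALSE, diff(pairs[, 1L]) == 1L & diff(pairs[, 2L]) == 1L)
  run_id <- cumsum(!step)
  runs <- split(seq_len(k), run_id)
  runs[lengths(runs) >= min_len]
}

#' One fragment-seeded refinement pass
#'
#' Collects the gapless fragments of an alignment, refits the
#' superposition on their union, and rebuilds the alignment by a fresh
#' scoring matrix and traceback over the same window.  If no fragment
#' survives (or fewer than 3 pairs do), the input alignment is returned
#' unchanged.
#'
#' @param pairs alignment pairs (template, window), 1-based.
#' @param template_xyz,window_xyz coordinates of the two sides.
#' @inheritParams score_matrix
#' @param min_frag fragment length threshold (default 10).
#' @return Refined k x 2 pair matrix.
#' @export
refine_alignment <- function(pairs, template_xyz, window_xyz, g = 3e-6,
                             d0_len = nrow(as_xyz(template_xyz)),
                             min_frag = 10L) {
  frags <- collect_fragments(pairs, min_frag)
  idx <- unlist(frags, use.names = FALSE)
  if (length(idx) < 3L) return(pairs)
  t_xyz <- as_xyz(template_xyz); w_xyz <- as_xyz(window_xyz)
  sup <- kabsch(t_xyz[pairs[idx, 1L], , drop = FALSE],
                w_xyz[pairs[idx, 2L], , drop = FALSE])
  dp_traceback(score_matrix(t_xyz, w_xyz, sup, g, d0_len))
}

#' Gapless threading of a template along the constant chain
#'
#' Slides the template over every contiguous window of its own length
#' on the constant chain (`L_c - L_t + 1` shifts, N- to C-terminus).
#' At each shift the gapless identity correspondence seeds a Kabsch
#' fit, a scoring-matrix traceback gives an alignment, and one
#' fragment-seeded refinement pass follows; the shift whose resulting
#' alignment scores the highest TM-score (under a Kabsch fit on its
#' pairs, normalised by `norm_len` with `d0(d0_len)`) wins.  Ties go to
#' the smaller shift.
#'
#' @param template_xyz,constant_xyz coordinates (or `ca_chain`s);
#'   template length must not exceed constant length.
#' @inheritParams score_matrix
#' @param norm_len TM-score normalisation length (default template
#'   length).
#' @param min_frag fragment length threshold.
#' @param shift_min smallest 0-based shift to consider (used by the
#'   multi-part combiner to keep parts in order).
#' @return List: `shift` (winning 0-based offset), `pairs` (template
#'   index, CONSTANT index, i.e. window pairs re-based by the shift),
#'   `sup`, `tm`.  `NULL` if no shift produced >= 3 aligned pairs.
#' @export
gapless_threading <- function(template_xyz, constant_xyz, g = 3e-6,
                              d0_len = nrow(as_xyz(template_xyz)),
                              norm_len = nrow(as_xyz(template_xyz)),
                              min_frag = 10L, shift_min = 0L) {
  t_xyz <- as_xyz(template_xyz); c_xyz <- as_xyz(constant_xyz)
  lt <- nrow(t_xyz); lc <- nrow(c_xyz)
  if (lt > lc)
    stop("template longer than constant: cannot thread")
  if (lt < 3L)
    stop("template too short to superpose (needs >= 3 residues)")
  best <- NULL
  for (s in shift_min:(lc - lt)) {
    w <- c_xyz[(s + 1L):(s + lt), , drop = FALSE]
    sup0 <- kabsch(t_xyz, w)
    pairs <- dp_traceback(score_matrix(t_xyz, w, sup0, g, d0_len))
    pairs <- refine_alignment(pairs, t_xyz, w, g, d0_len, min_frag)
    if (nrow(pairs) < 3L) next
    sup <- kabsch(t_xyz[pairs[, 1L], , drop = FALSE],
                  w[pairs[, 2L], , drop = FALSE])
    d <- pair_distances(sup, t_xyz[pairs[, 1L], , drop = FALSE],
                        w[pairs[, 2L], , drop = FALSE])
    tm <- tm_score(d, norm_len, d0_len)
    if (is.null(best) || tm > best$tm) {
      gp <- cbind(template = pairs[, 1L], constant = pairs[, 2L] + s)
      best <- list(shift = s, pairs = gp, sup = sup, tm = tm)
    }
  }
  best
}

#' Split a template into k equal contiguous parts
#'
#' Base size `floor(L/k)`; the first `L mod k` parts take one extra
#' residue.  Parts are contiguous, non-overlapping and cover the
#' template.
#'
#' @param L template length.
#' @param k number of parts, one of 1, 2, 3, 5, 8; must not exceed `L`.
#' @return k x 2 integer matrix of 1-based (start, end) boundaries, or
#'   `NULL` when `k > L` (the group is skipped, not an error).
#' @export
split_parts <- function(L, k) {
  if (!k %in% c(1L, 2L, 3L, 5L, 8L))
    stop("k must be one of 1, 2, 3, 5, 8")
  if (k > L) return(NULL)
  base <- L %/% k
  sizes <- rep(base, k) + c(rep(1L, L %% k), rep(0L, k - L %% k))
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

# Run one part-group: thread each part in template order over
# constant regions at or after the previous part's winning window end,
# and pool the aligned pairs.
run_part_group <- function(t_xyz, c_xyz, bounds, g, d0_len, min_frag) {
  lc <- nrow(c_xyz)
  prev_end <- 0L
  pooled <- NULL
  for (p in seq_len(nrow(bounds))) {
    a <- bounds[p, 1L]; b <- bounds[p, 2L]
    lp <- b - a + 1L
    if (prev_end > lc - lp) next          # no window room left: part skipped
    hit <- gapless_threading(t_xyz[a:b, , drop = FALSE], c_xyz, g,
                             d0_len = d0_len, norm_len = lp,
                             min_frag = min_frag, shift_min = prev_end)
    if (is.null(hit)) next
    part_pairs <- cbind(template = hit$pairs[, 1L] + a - 1L,
                        constant = hit$pairs[, 2L])
    pooled <- rbind(pooled, part_pairs)
    prev_end <- hit$shift + lp
  }
  if (is.null(pooled)) return(NULL)
  # enforce global strict monotonicity; earlier parts keep their pairs
  keep <- rep(TRUE, nrow(pooled))
  last_i <- 0L; last_j <- 0L
  for (r in seq_len(nrow(pooled))) {
    if (pooled[r, 1L] > last_i && pooled[r, 2L] > last_j) {
      last_i <- pooled[r, 1L]; last_j <- pooled[r, 2L]
    } else keep[r] <- FALSE
  }
  pooled[keep, , drop = FALSE]
}

#' Full pairwise residue-level alignment
#'
#' The complete phase-2 engine.  The shorter chain becomes the
#' template; for each part-group k in `parts` (groups with k above the
#' template length, or with parts shorter than 3 residues, are
#' skipped) the template parts are threaded in sequence order over
#' disjoint, ordered regions of the constant chain, their aligned pairs
#' are pooled, and the group is scored by one joint TM-score-optimal
#' superposition over the pooled pairs, normalised by the template
#' length.  The group with the highest TM-score is reported.
#'
#' @param chain_a,chain_b `ca_chain` objects (>= 5 residues each).
#' @param gap_penalty gap move increment g of the scoring matrix
#'   (default 3e-6; try 0.08 for structural analogs).
#' @param parts part-group sizes to try (subset of {1,2,3,5,8}).
#' @param min_frag fragment length threshold (default 10).
#' @return Object of class `residue_alignment`: `pairs` (template index,
#'   constant index), `superposition`, `tm`, `rmsd`, `n_ali`,
#'   `gap_penalty`, `parts_used`, `template_is_first`, and the two
#'   chain lengths.
#' @examples
#' ch <- make_chain(30, "helix", seed = 1)
#' align_pair(ch, ch)$tm    # 1 for self-alignment
#' @export
align_pair <- function(chain_a, chain_b, gap_penalty = 3e-6,
                       parts = c(1L, 2L, 3L, 5L, 8L), min_frag = 10L) {
  if (length(chain_a) < 5L || length(chain_b) < 5L)
    stop("both chains need at least 5 residues")
  tc <- choose_template(chain_a, chain_b)
  t_xyz <- as_xyz(tc$template); c_xyz <- as_xyz(tc$constant)
  lt <- nrow(t_xyz)
  best <- NULL
  for (k in sort(unique(as.integer(parts)))) {
    bounds <- split_parts(lt, k)
    if (is.null(bounds)) next
    if (min(bounds[, 2L] - bounds[, 1L] + 1L) < 3L) next
    pooled <- run_part_group(t_xyz, c_xyz, bounds, gap_penalty, lt, min_frag)
    if (is.null(pooled) || nrow(pooled) < 3L) next
    opt <- tm_score_optimal(t_xyz[pooled[, 1L], , drop = FALSE],
                            c_xyz[pooled[, 2L], , drop = FALSE],
                            l_norm = lt)
    if (is.null(best) || opt$tm > best$tm) {
      best <- list(pairs = pooled, superposition = opt$sup, tm = opt$tm,
                   rmsd = rmsd(opt$d), n_ali = nrow(pooled),
                   gap_penalty = gap_penalty, parts_used = k,
                   template_is_first = tc$template_is_first,
                   template_length = lt, constant_length = nrow(c_xyz))
    }
  }
  if (is.null(best))
    stop("no part-group produced an alignment (chains too short or degenerate)")
  class(best) <- "residue_alignment"
  best
}

#' @export
print.residue_alignment <- function(x, ...) {
  cat(sprintf(
    "<residue_alignment> TM-score %.3f  RMSD %.3f A  N_ali %d  (template L=%d, constant L=%d, %d part%s, g=%g)\n",
    x$tm, x$rmsd, x$n_ali, x$template_length, x$constant_length,
    x$parts_used, if (x$parts_used > 1L) "s" else "", x$gap_penalty))
  invisible(x)
}
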