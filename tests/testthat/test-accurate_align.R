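test_that("template choice picks the shorter chain, first on ties", {
  short <- make_chain(10, "helix")
  long <- make_chain(20, "helix")
  expect_true(choose_template(short, long)$template_is_first)
  expect_false(choose_template(long, short)$template_is_first)
  expect_true(choose_template(short, short)$template_is_first)
})

test_that("scoring matrix follows the gap/match recurrence exactly", {
  idt <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                   class = "superposition")
  w <- make_chain(5, "helix")$xyz
  sm <- score_matrix(w, w, idt, g = 3e-6, d0_len = 5)
  expect_true(all(sm$M[1L, ] == 0) && all(sm$M[, 1L] == 0))
  # perfectly superposed identical windows: diagonal accumulates 1 per match
  expect_equal(diag(sm$M)[-1L], as.numeric(1:5), tolerance = 1e-9)

  # single residue at distance exactly d0: M[1,1] = max(g, 0.5)
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(d0(30), 0, 0), 1)
  sm1 <- score_matrix(a, b, idt, g = 3e-6, d0_len = 30)
  expect_equal(sm1$M[2L, 2L], 0.5, tolerance = 1e-12)
})

test_that("traceback of the scoring matrix is a strictly monotone optimal path", {
  idt <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                   class = "superposition")
  w <- make_chain(5, "strand")$xyz
  p <- dp_traceback(score_matrix(w, w, idt, g = 3e-6, d0_len = 5))
  expect_equal(unname(p), cbind(1:5, 1:5))

  one <- score_matrix(matrix(0, 1, 3), matrix(0, 1, 3), idt, g = 3e-6,
                      d0_len = 1)
  expect_equal(unname(dp_traceback(one)), cbind(1L, 1L))
})

test_that("DP score equals brute-force enumeration over all monotone paths", {
  set.seed(17)
  for (rep in 1:8) {
    m <- sample(3:6, 1L); n <- sample(3:8, 1L)
    term <- matrix(runif(m * n), m, n)
    g <- sample(c(3e-6, 0.08, -0.5), 1L)
    sm <- structure(list(M = pdbalign:::cpp_fill_m(term, g), term = term,
                         g = g), class = "score_matrix")
    expect_equal(sm$M[m + 1L, n + 1L], oracle_dp_max(term, g),
                 tolerance = 1e-9)
    p <- dp_traceback(sm)
    if (nrow(p) > 1L) {
      expect_true(all(diff(p[, 1L]) > 0))
      expect_true(all(diff(p[, 2L]) > 0))
    }
  }
})

test_that("fragment collection keeps maximal gapless runs of >= min_len", {
  run <- function(i0, j0, len) cbind(i0:(i0 + len - 1L), j0:(j0 + len - 1L))
  expect_length(collect_fragments(run(1, 1, 12)), 1L)
  expect_length(collect_fragments(run(1, 1, 9)), 0L)      # boundary: < 10
  expect_length(collect_fragments(run(1, 1, 10)), 1L)
  two <- rbind(run(1, 1, 10), run(12, 13, 15))
  fr <- collect_fragments(two)
  expect_equal(lengths(fr), c(10L, 15L), ignore_attr = TRUE)
  expect_length(collect_fragments(matrix(integer(0), 0, 2)), 0L)
})

test_that("fragment-seeded refinement never worsens a tail-skewed alignment", {
  ch <- make_chain(40, "mixed", seed = 31)
  A <- ch$xyz
  B <- A
  B[36:40, ] <- B[36:40, ] + 30          # displaced tail skews the global fit
  sup0 <- kabsch(A, B)
  sm <- score_matrix(A, B, sup0, g = 3e-6, d0_len = 40)
  p0 <- dp_traceback(sm)
  p1 <- refine_alignment(p0, A, B, g = 3e-6, d0_len = 40)
  tm_of <- function(p) {
    s <- kabsch(A[p[, 1L], , drop = FALSE], B[p[, 2L], , drop = FALSE])
    tm_score(pair_dist_for_test(s, A[p[, 1L], , drop = FALSE],
                                B[p[, 2L], , drop = FALSE]), 40)
  }
  expect_gte(tm_of(p1), tm_of(p0))
  # no fragments -> input returned unchanged
  few <- cbind(c(1L, 5L, 9L), c(2L, 6L, 10L))
  expect_identical(refine_alignment(few, A, B), few)
})

test_that("gapless threading enumerates L_c - L_t + 1 windows and recovers planted offsets", {
  tpl <- make_chain(30, "mixed", seed = 41)
  # exact substructure at several offsets, including both ends
  for (off in c(0L, 3L, 40L)) {
    dec <- make_decoy_with_embedded_template(tpl, off, 70, seed = 50 + off)
    hit <- gapless_threading(tpl, dec)
    expect_equal(hit$shift, off)
    expect_equal(hit$tm, 1.0, tolerance = 1e-9)
    expect_equal(nrow(hit$pairs), 30L)
  }
  # L_t = L_c: single shift, equals the direct alignment
  hit <- gapless_threading(tpl, tpl)
  expect_equal(hit$shift, 0L)
  expect_equal(hit$tm, 1.0, tolerance = 1e-12)
  expect_error(gapless_threading(make_chain(10, "helix"),
                                 make_chain(5, "helix")), "thread")
})

test_that("template splitting balances part sizes with the remainder rule", {
  expect_equal(split_parts(40, 5)[, 2] - split_parts(40, 5)[, 1] + 1,
               rep(8L, 5), ignore_attr = TRUE)
  s41 <- split_parts(41, 5)
  expect_equal(s41[, 2] - s41[, 1] + 1, c(9L, 8L, 8L, 8L, 8L),
               ignore_attr = TRUE)
  expect_equal(unname(s41[1, 1]), 1L)
  expect_equal(unname(s41[5, 2]), 41L)
  expect_null(split_parts(7, 8))         # k > L: group skipped
  expect_error(split_parts(40, 4), "one of")
})

test_that("self-alignment is perfect and the pair list is monotone", {
  ch <- make_chain(35, "mixed", seed = 61)
  aln <- align_pair(ch, ch)
  expect_equal(aln$tm, 1.0, tolerance = 1e-9)
  expect_equal(aln$n_ali, 35L)
  expect_lt(aln$rmsd, 1e-6)
  expect_equal(aln$parts_used, 1L)
  expect_true(all(diff(aln$pairs[, 1L]) > 0))
  expect_true(all(diff(aln$pairs[, 2L]) > 0))
})

test_that("alignment quality is symmetric in the argument order", {
  a <- make_chain(25, "mixed", seed = 71)
  b <- make_chain(40, "mixed", seed = 72)
  f <- align_pair(a, b)
  r <- align_pair(b, a)
  expect_equal(f$tm, r$tm, tolerance = 1e-9)
  expect_equal(f$n_ali, r$n_ali)
  expect_true(f$template_is_first)
  expect_false(r$template_is_first)
})

test_that("multi-part groups win on a split-embedding fixture and the max is reported", {
  tpl <- make_chain(40, "mixed", seed = 81)
  dec <- make_split_decoy(tpl, gap_len = 15, flank_len = 5, seed = 82)
  single <- align_pair(tpl, dec, parts = 1)
  multi <- align_pair(tpl, dec, parts = c(1, 2))
  expect_gt(multi$tm, single$tm)
  expect_gte(multi$parts_used, 2L)
  full <- align_pair(tpl, dec)
  expect_gte(full$tm, multi$tm)          # enlarging the group set: monotone max
  expect_gte(full$tm, single$tm)
})

test_that("rigid noisy copies align with high TM-score at any embedding", {
  tpl <- make_chain(28, "mixed", seed = 91)
  dec <- make_decoy_with_embedded_template(tpl, 11, 60, seed = 92)
  aln <- align_pair(tpl, dec)
  expect_gte(aln$tm, 0.95)
  expect_equal(aln$n_ali, 28L)
})
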