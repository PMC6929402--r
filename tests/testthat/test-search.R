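# A small in-memory database of distinct synthetic chains.  Noise makes
# every entry unique even within a motif class.
make_test_db <- function(n_entries = 12L, n_min = 20L, seed0 = 1000L) {
  motifs <- c("helix", "strand", "mixed")
  db <- lapply(seq_len(n_entries), function(i) {
    make_chain(n_min + (i %% 4L) * 3L, motifs[1L + (i %% 3L)],
               noise_sigma = 0.25, seed = seed0 + i,
               structure_id = sprintf("d%03d", i))
  })
  names(db) <- sprintf("d%03d_A", seq_len(n_entries))
  db
}

test_that("searching a database containing the query ranks it first with TM 1", {
  db <- make_test_db()
  hits <- search_one_vs_all(db[[5L]], db, search_params())
  expect_equal(nrow(hits), length(db))
  top <- hits[hits$rank == 1L, ]
  expect_equal(top$db_id, names(db)[5L])
  expect_equal(top$tm, 1.0, tolerance = 1e-9)
  expect_true(top$passed_filter)
})

test_that("entries failing the filter carry no phase-2 metrics", {
  db <- make_test_db()
  q <- db[[1L]]                       # a helix: strand entries share no SSE
  hits <- search_one_vs_all(q, db, search_params())
  failed <- hits[!hits$passed_filter, ]
  expect_gt(nrow(failed), 0L)
  expect_true(all(is.na(failed$tm)))
  expect_true(all(is.na(failed$rmsd)))
  expect_true(all(is.na(failed$n_ali)))
  passed <- hits[hits$passed_filter, ]
  expect_true(all(!is.na(passed$tm)))
  # ranking: tm descending among survivors, failures after, id ascending
  expect_true(all(diff(passed$rank) == 1L))
  expect_equal(order(-passed$tm, passed$db_id), seq_len(nrow(passed)))
  expect_false(is.unsorted(failed$db_id))
})

test_that("results are identical for any worker count", {
  db <- make_test_db()
  h1 <- search_one_vs_all(db[[2L]], db, search_params(workers = 1L))
  h4 <- search_one_vs_all(db[[2L]], db, search_params(workers = 4L))
  expect_identical(h1, h4)
  a1 <- all_vs_all(db[1:6], search_params(workers = 1L))
  a4 <- all_vs_all(db[1:6], search_params(workers = 4L))
  expect_identical(a1, a4)
})

test_that("all-vs-all enumerates each unordered pair once with consistent summaries", {
  db <- make_test_db(5L)
  res <- all_vs_all(db, search_params())
  expect_equal(nrow(res), 10L)                     # 5*4/2
  expect_true(all(res$id_a < res$id_b))
  s <- attr(res, "summary")
  done <- !is.na(res$tm)
  expect_equal(s$n_pairs, 10L)
  expect_equal(s$n_passed, sum(res$passed_filter))
  expect_equal(s$mean_tm_completed, mean(res$tm[done]))
  expect_equal(s$mean_rmsd_completed, mean(res$rmsd[done]))
  expect_equal(s$mean_tm_all, sum(res$tm[done]) / nrow(res))

  res2 <- all_vs_all(make_test_db(2L), search_params())
  expect_equal(nrow(res2), 1L)
  expect_error(all_vs_all(make_test_db(1L)), "at least 2")
})

test_that("phase 2 can be disabled for filter-only screening", {
  db <- make_test_db(6L)
  res <- all_vs_all(db, search_params(phase2 = FALSE))
  expect_true(all(is.na(res$tm)))
  expect_gt(sum(res$passed_filter), 0L)
})

test_that("reports round-trip through the TSV format", {
  db <- make_test_db()
  hits <- search_one_vs_all(db[[3L]], db, search_params())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(hits, f)
  lines <- readLines(f)
  expect_equal(lines[1L],
               "rank\tdb_id\ttm\trmsd\tn_ali\tlcs_length\tpassed_filter")
  top <- strsplit(lines[2L], "\t")[[1L]]
  expect_equal(top[3L], "1.000")
  expect_equal(top[4L], "0.000")
  back <- read_report(f)
  expect_equal(back$db_id, hits$db_id)             # identical ranking
  expect_equal(back$rank, hits$rank)
  expect_equal(back$passed_filter, hits$passed_filter)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(hits[0L, ], f2)
  expect_equal(length(readLines(f2)), 1L)          # header-only
})

test_that("a PDB directory round-trips through read_db with an SSE cache", {
  dir <- withr::local_tempdir()
  db <- make_test_db(4L)
  for (id in names(db))
    write_chain_pdb(db[[id]], file.path(dir, paste0(db[[id]]$structure_id,
                                                    ".pdb")))
  loaded <- read_db(dir)
  expect_equal(length(loaded), 4L)
  expect_equal(sort(names(loaded)), sort(names(db)))
  for (id in names(db))
    expect_equal(loaded[[id]]$chain$xyz, db[[id]]$xyz, tolerance = 5e-4)

  cache <- file.path(dir, "sse.cache")
  write_sse_cache(loaded, cache)
  reloaded <- read_db(dir, sse_cache = cache)
  expect_identical(lapply(reloaded, `[[`, "sse"),
                   lapply(loaded, `[[`, "sse"))

  writeLines("garbage not a pdb", file.path(dir, "broken.pdb"))
  expect_warning(read_db(dir), "skipping")
})
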