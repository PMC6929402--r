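# One-against-all and all-against-all structural neighbour search.
# Phase 1 (SSE-string LCS filter) runs on every entry; phase 2 (the
# residue-level aligner) only on entries that pass.  Each pair is an
# independent pure task, so results are identical for any worker count.

#' Search parameter set
#'
#' Defaults follow the method's published settings: filter factor 0.7,
#' gap penalty 3e-6 (0.08 suits structurally analogous pairs), part
#' groups {1, 2, 3, 5, 8}, fragment threshold 10.
#'
#' @param filter_factor phase-1 threshold fraction of `min(m, n)`.
#' @param gap_penalty scoring-matrix gap increment.
#' @param parts part-group sizes to try.
#' @param min_frag fragment length threshold.
#' @param workers number of parallel workers (forked; results do not
#'   depend on this).
#' @param phase2 run the residue-level aligner on filter survivors
#'   (disable to benchmark or inspect the filter alone).
#' @return List of class `search_params`.
#' @export
search_params <- function(filter_factor = 0.7, gap_penalty = 3e-6,
                          parts = c(1L, 2L, 3L, 5L, 8L), min_frag = 10L,
                          workers = 1L, phase2 = TRUE) {
  stopifnot(filter_factor > 0, filter_factor <= 1, workers >= 1L)
  structure(list(filter_factor = filter_factor, gap_penalty = gap_penalty,
                 parts = as.integer(parts), min_frag = as.integer(min_frag),
                 workers = as.integer(workers), phase2 = isTRUE(phase2)),
            class = "search_params")
}

# A database is a named list of entries, each list(chain=, sse=).
as_db_entry <- function(x, id = NULL) {
  if (inherits(x, "ca_chain")) {
    s <- attr(x, "sse")
    if (is.null(s)) s <- assign_sse_from_ca(x)
    x <- list(chain = x, sse = s)
  }
  stopifnot(inherits(x$chain, "ca_chain"), is.character(x$sse))
  x
}

db_ids <- function(db) {
  ids <- names(db)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(seq_along(db), function(i) {
      ch <- if (inherits(db[[i]], "ca_chain")) db[[i]] else db[[i]]$chain
      id <- paste0(ch$structure_id, "_", ch$chain_id)
      if (nzchar(id) && id != "_") id else sprintf("entry%04d", i)
    }, "")
  make.unique(ids)
}

#' Read a directory of PDB files as a search database
#'
#' One entry per (file, chain); secondary-structure strings come from a
#' sidecar cache when present (see [write_sse_cache()]), otherwise from
#' the geometric assigner.  Unreadable files are skipped with a
#' warning, not an error.
#'
#' @param dir directory containing `.pdb`/`.ent` files.
#' @param sse_cache optional path of an SSE cache file.
#' @return Named list of entries `list(chain, sse)`.
#' @export
read_db <- function(dir, sse_cache = NULL) {
  files <- sort(list.files(dir, pattern = "\\.(pdb|ent)$", full.names = TRUE,
                           ignore.case = TRUE))
  cache <- if (!is.null(sse_cache) && file.exists(sse_cache))
    read_sse_cache(sse_cache) else NULL
  db <- list()
  for (f in files) {
    chains <- tryCatch(list_chains(f), error = function(e) {
      warning("skipping unreadable database entry ", f, ": ",
              conditionMessage(e)); character(0)
    })
    if (length(chains) == 0L)
      warning("skipping database entry with no C-alpha records: ", f)
    for (cid in chains) {
      ch <- tryCatch(read_pdb_chain(f, cid), error = function(e) NULL)
      if (is.null(ch)) next
      id <- paste0(sub("\\.(pdb|ent)$", "", basename(f), ignore.case = TRUE),
                   "_", cid)
      key <- paste0(basename(f), "\t", cid)
      sse <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
             else assign_sse_from_ca(ch)
      db[[id]] <- list(chain = ch, sse = sse)
    }
  }
  db
}

# Run FUN over seq_len(n); forked workers when asked for and worthwhile.
# Order (and hence output) never depends on the worker count.
par_map <- function(n, FUN, workers) {
  if (workers > 1L && n > 8L && .Platform$OS.type == "unix")
    parallel::mclapply(seq_len(n), FUN, mc.cores = workers,
                       mc.preschedule = TRUE)
  else
    lapply(seq_len(n), FUN)
}

align_fields <- function(aln) {
  list(tm = aln$tm, rmsd = aln$rmsd, n_ali = aln$n_ali)
}

#' One-against-all structural neighbour search
#'
#' Phase 1 scores the query's SSE string against every database entry
#' by LCS length; entries passing the `min(m, n) * factor` threshold
#' get the full residue-level alignment.  Hits are ranked by TM-score
#' descending, then id ascending; entries that fail the filter carry no
#' phase-2 fields and rank after all survivors.
#'
#' @param query a `ca_chain` (optionally with an `sse` attribute) or
#'   `list(chain, sse)`.
#' @param db named list of entries (`ca_chain`s or `list(chain, sse)`),
#'   e.g. from [read_db()].
#' @param params a [search_params()] object.
#' @return `data.frame` with columns rank, db_id, tm, rmsd, n_ali,
#'   lcs_length, passed_filter.
#' @export
search_one_vs_all <- function(query, db, params = search_params()) {
  if (length(db) == 0L) stop("empty database")
  q <- as_db_entry(query)
  ids <- db_ids(db)
  m <- nchar(q$sse)
  one <- function(i) {
    e <- as_db_entry(db[[i]])
    n <- nchar(e$sse)
    lcs <- lcs_length(q$sse, e$sse)
    pass <- passes_filter(lcs, m, n, params$filter_factor)
    res <- list(db_id = ids[i], lcs_length = lcs, passed_filter = pass,
                tm = NA_real_, rmsd = NA_real_, n_ali = NA_integer_)
    if (pass && params$phase2) {
      aln <- tryCatch(
        align_pair(q$chain, e$chain, params$gap_penalty, params$parts,
                   params$min_frag),
        error = function(err) NULL)
      if (!is.null(aln)) {
        res$tm <- aln$tm; res$rmsd <- aln$rmsd; res$n_ali <- aln$n_ali
      }
    }
    res
  }
  rows <- par_map(length(db), one, params$workers)
  out <- data.frame(
    db_id = vapply(rows, `[[`, "", "db_id"),
    tm = vapply(rows, `[[`, 0, "tm"),
    rmsd = vapply(rows, `[[`, 0, "rmsd"),
    n_ali = vapply(rows, `[[`, 0L, "n_ali"),
    lcs_length = vapply(rows, `[[`, 0L, "lcs_length"),
    passed_filter = vapply(rows, `[[`, TRUE, "passed_filter"),
    stringsAsFactors = FALSE)
  key_tm <- ifelse(is.na(out$tm), -Inf, out$tm)
  out <- out[order(-key_tm, out$db_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' All-against-all pairwise alignment over a database
#'
#' Evaluates every unordered pair exactly once (`n*(n-1)/2` pairs).
#' Each pair goes through the phase-1 filter and, when it passes and
#' `params$phase2` is on, the residue-level aligner.
#'
#' @param db named list of entries (>= 2).
#' @param params a [search_params()] object.
#' @return `data.frame` with one row per pair (id_a, id_b, lcs_length,
#'   passed_filter, tm, rmsd, n_ali) and attribute `summary`: list with
#'   `n_pairs`, `n_passed`, `mean_tm_completed`, `mean_rmsd_completed`
#'   (means over phase-2-completed pairs) and `mean_tm_all` (failed
#'   pairs counted as 0).
#' @export
all_vs_all <- function(db, params = search_params()) {
  if (length(db) < 2L) stop("all-vs-all needs at least 2 entries")
  ids <- db_ids(db)
  entries <- lapply(db, as_db_entry)
  idx <- combn(length(db), 2L)
  one <- function(p) {
    i <- idx[1L, p]; j <- idx[2L, p]
    a <- entries[[i]]; b <- entries[[j]]
    lcs <- lcs_length(a$sse, b$sse)
    pass <- passes_filter(lcs, nchar(a$sse), nchar(b$sse),
                          params$filter_factor)
    res <- list(id_a = ids[i], id_b = ids[j], lcs_length = lcs,
                passed_filter = pass, tm = NA_real_, rmsd = NA_real_,
                n_ali = NA_integer_)
    if (pass && params$phase2) {
      aln <- tryCatch(
        align_pair(a$chain, b$chain, params$gap_penalty, params$parts,
                   params$min_frag),
        error = function(err) NULL)
      if (!is.null(aln)) {
        res$tm <- aln$tm; res$rmsd <- aln$rmsd; res$n_ali <- aln$n_ali
      }
    }
    res
  }
  rows <- par_map(ncol(idx), one, params$workers)
  out <- data.frame(
    id_a = vapply(rows, `[[`, "", "id_a"),
    id_b = vapply(rows, `[[`, "", "id_b"),
    lcs_length = vapply(rows, `[[`, 0L, "lcs_length"),
    passed_filter = vapply(rows, `[[`, TRUE, "passed_filter"),
    tm = vapply(rows, `[[`, 0, "tm"),
    rmsd = vapply(rows, `[[`, 0, "rmsd"),
    n_ali = vapply(rows, `[[`, 0L, "n_ali"),
    stringsAsFactors = FALSE)
  done <- !is.na(out$tm)
  attr(out, "summary") <- list(
    n_pairs = nrow(out),
    n_passed = sum(out$passed_filter),
    mean_tm_completed = if (any(done)) mean(out$tm[done]) else NA_real_,
    mean_rmsd_completed = if (any(done)) mean(out$rmsd[done]) else NA_real_,
    mean_tm_all = mean(ifelse(done, out$tm, 0)))
  out
}

#' Write a ranked hit report
#'
#' Tab-separated, one row per hit, floats at 3 decimals,
#' `passed_filter` as `true`/`false`; phase-2 fields of entries that
#' failed the filter are written as `NA`.
#'
#' @param hits data.frame from [search_one_vs_all()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(hits, path) {
  fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  fmti <- function(x) ifelse(is.na(x), "NA", as.character(x))
  lines <- c(
    paste(c("rank", "db_id", "tm", "rmsd", "n_ali", "lcs_length",
            "passed_filter"), collapse = "\t"),
    if (nrow(hits) > 0L)
      paste(hits$rank, hits$db_id, fmt3(hits$tm), fmt3(hits$rmsd),
            fmti(hits$n_ali), hits$lcs_length,
            ifelse(hits$passed_filter, "true", "false"), sep = "\t"))
  con <- file(path, "wb")   # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read back a hit report
#'
#' @param path a file written by [write_report()].
#' @return `data.frame` with the report columns.
#' @export
read_report <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  out$passed_filter <- out$passed_filter == "true" | out$passed_filter == TRUE
  out
}

#' Write / read a secondary-structure cache
#'
#' Plain-text sidecar amortising phase-1 string assignment across
#' queries: one line per chain, `<file>\t<chain>\t<SSE string>`.
#'
#' @param db named list of entries whose chains carry `structure_id`.
#' @param path cache file path.
#' @return `path` invisibly (`write_sse_cache`); named list keyed by
#'   `<file>\t<chain>` (`read_sse_cache`).
#' @export
write_sse_cache <- function(db, path) {
  lines <- vapply(db, function(e) {
    e <- as_db_entry(e)
    paste(paste0(e$chain$structure_id, ".pdb"), e$chain$chain_id, e$sse,
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sse_cache
#' @export
read_sse_cache <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, `[[`, 3L)
  names(out) <- vapply(parts, function(p) paste0(p[1L], "\t", p[2L]), "")
  out
}
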