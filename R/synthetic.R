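# Synthetic C-alpha traces with known ground truth: idealised helices,
# strands and self-avoiding coils, optionally noised and rigidly moved.
# Every stage of the aligner can be exercised against planted answers
# without downloading any structure.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.  NULL seed uses the current
# stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random proper rotation matrix
#'
#' QR decomposition of a standard-normal 3 x 3 matrix, sign-fixed to a
#' uniform proper rotation (det +1).
#'
#' @param seed optional RNG seed (the caller's RNG state is preserved).
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_ <- qr(matrix(rnorm(9), 3L))
    R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    R
  })
}

# Uniform random rigid motion (rotation + translation within +-20 A).
random_superposition <- function() {
  structure(list(rotation = random_rotation(),
                 translation = runif(3L, -20, 20)),
            class = "superposition")
}

# Ideal alpha-helix: rise 1.5 A/residue, radius 2.3 A, 100 deg/residue.
helix_coords <- function(n) {
  t <- seq_len(n) - 1L
  a <- t * 100 * pi / 180
  cbind(2.3 * cos(a), 2.3 * sin(a), 1.5 * t)
}

# Extended strand: planar zig-zag with 3.8 A steps and a 6.7 A
# i -> i+2 distance.
strand_coords <- function(n) {
  t <- seq_len(n) - 1L
  ax <- 6.7 / 2
  ay <- sqrt(3.8^2 - ax^2)
  cbind(ax * t, ay * (t %% 2), rep(0, n))
}

# Self-avoiding random walk with 3.8 A steps; non-bonded pairs kept
# > 3.5 A apart by rejection sampling (falls back to the least-clashing
# candidate on pathological dead ends, which keeps the walk finite).
coil_coords <- function(n) {
  xyz <- matrix(0, n, 3L)
  if (n == 1L) return(xyz)
  for (i in 2:n) {
    best <- NULL; best_min <- -Inf
    for (try in seq_len(60L)) {
      v <- rnorm(3L)
      cand <- xyz[i - 1L, ] + 3.8 * v / sqrt(sum(v^2))
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      dmin <- if (nrow(prev) == 0L) Inf
              else sqrt(min(rowSums(sweep(prev, 2L, cand)^2)))
      if (dmin > 3.5) { best <- cand; break }
      if (dmin > best_min) { best_min <- dmin; best <- cand }
    }
    xyz[i, ] <- best
  }
  xyz
}

motif_segments <- function(n_res, motif) {
  switch(motif,
    helix  = list(list(code = "H", n = n_res)),
    strand = list(list(code = "E", n = n_res)),
    coil   = list(list(code = "C", n = n_res)),
    mixed  = {
      nh <- max(1L, round(0.4 * n_res))
      ne <- max(1L, round(0.3 * n_res))
      nc <- n_res - nh - ne
      segs <- list(list(code = "H", n = nh))
      if (nc > 0L) segs <- c(segs, list(list(code = "C", n = nc)))
      c(segs, list(list(code = "E", n = ne)))
    },
    stop("unknown motif: ", motif))
}

segment_coords <- function(code, n) {
  switch(code,
         H = helix_coords(n),
         E = strand_coords(n),
         C = coil_coords(n))
}

#' Generate a synthetic C-alpha chain with known secondary structure
#'
#' Builds an idealised trace: `helix` (rise 1.5 A, radius 2.3 A,
#' 100 deg/residue), `strand` (3.8 A zig-zag), `coil` (self-avoiding
#' 3.8 A random walk), or `mixed` (helix + coil + strand segments,
#' roughly 40/30/30, joined with random orientations).  Gaussian
#' coordinate noise and a rigid motion can then be applied.  Identical
#' seeds give identical chains.
#'
#' @param n_res number of residues (>= 1).
#' @param motif one of `"helix"`, `"strand"`, `"coil"`, `"mixed"`.
#' @param noise_sigma standard deviation (Angstrom) of isotropic
#'   Gaussian noise added per coordinate.
#' @param seed optional RNG seed; the caller's RNG state is preserved.
#' @param transform optional `superposition` applied after noising; the
#'   string `"random"` draws a random rigid motion.
#' @param structure_id,chain_id identifiers for the resulting chain.
#' @return A `ca_chain` with attributes `sse` (ground-truth 4-state
#'   string) and `transform` (the rigid motion applied, or `NULL`).
#' @export
make_chain <- function(n_res, motif = c("helix", "strand", "coil", "mixed"),
                       noise_sigma = 0, seed = NULL, transform = NULL,
                       structure_id = paste0("synth_", motif[1L]),
                       chain_id = "A") {
  motif <- match.arg(motif)
  stopifnot(n_res >= 1L, noise_sigma >= 0)
  with_seed(seed, {
    segs <- motif_segments(n_res, motif)
    xyz <- NULL
    sse <- character(0)
    for (s in segs) {
      seg <- segment_coords(s$code, s$n)
      if (is.null(xyz)) {
        xyz <- seg
      } else {
        # join: random orientation, first atom one bond beyond the tail
        R <- random_rotation()
        seg <- sweep(seg, 2L, seg[1L, ]) %*% t(R)
        v <- rnorm(3L)
        start <- xyz[nrow(xyz), ] + 3.8 * v / sqrt(sum(v^2))
        seg <- sweep(seg, 2L, start, "+")
        xyz <- rbind(xyz, seg)
      }
      sse <- c(sse, rep(s$code, s$n))
    }
    if (noise_sigma > 0)
      xyz <- xyz + matrix(rnorm(3L * n_res, 0, noise_sigma), n_res, 3L)
    if (identical(transform, "random")) transform <- random_superposition()
    if (!is.null(transform)) xyz <- apply_superposition(transform, xyz)
    ch <- new_chain(xyz, structure_id = structure_id, chain_id = chain_id)
    attr(ch, "sse") <- paste(sse, collapse = "")
    attr(ch, "transform") <- transform
    ch
  })
}

#' Plant a rigid copy of a template inside a coil decoy
#'
#' Builds a constant chain of `n_total` residues whose window
#' `[offset+1, offset+L_t]` (0-based `offset`) is an exact rigid copy
#' of the template; the flanks are self-avoiding coil.  Gapless
#' threading should recover `offset` as the winning shift.
#'
#' @param template a `ca_chain` to embed.
#' @param offset 0-based start of the embedded window.
#' @param n_total total decoy length (`offset + length(template)` at
#'   most).
#' @param seed optional RNG seed.
#' @param transform rigid motion applied to the template copy; `NULL`
#'   (default) draws a random rotation and centres the copy on the
#'   replaced window.
#' @return A `ca_chain` with attributes `offset` and `transform`.
#' @export
make_decoy_with_embedded_template <- function(template, offset, n_total,
                                              seed = NULL, transform = NULL) {
  t_xyz <- as_xyz(template)
  lt <- nrow(t_xyz)
  if (offset < 0L || offset + lt > n_total)
    stop("offset must satisfy 0 <= offset and offset + L_t <= n_total")
  with_seed(seed, {
    base <- coil_coords(n_total)
    win <- (offset + 1L):(offset + lt)
    if (is.null(transform)) {
      R <- random_rotation()
      tr <- colMeans(base[win, , drop = FALSE]) - as.numeric(R %*% colMeans(t_xyz))
      transform <- structure(list(rotation = R, translation = tr),
                             class = "superposition")
    }
    base[win, ] <- apply_superposition(transform, t_xyz)
    ch <- new_chain(base, structure_id = "synth_decoy")
    attr(ch, "offset") <- offset
    attr(ch, "transform") <- transform
    ch
  })
}

#' Decoy with the two template halves planted around an insertion
#'
#' Embeds the first and second halves of the template as rigid copies
#' under ONE shared rigid motion, separated by `gap_len` extra coil
#' residues, with coil flanks of `flank_len` on both sides.  A single
#' contiguous threading window of the full template length cannot cover
#' both halves, while a 2-part split recovers each half exactly and a
#' joint superposition fits both; multi-part alignment therefore beats
#' the single-part alignment on this fixture.
#'
#' @param template a `ca_chain` (>= 6 residues).
#' @param gap_len number of coil residues inserted between the halves.
#' @param flank_len coil residues before the first and after the second
#'   half.
#' @param seed optional RNG seed.
#' @return A `ca_chain` with attributes `offsets` (0-based window
#'   starts of the two halves) and `transform`.
#' @export
make_split_decoy <- function(template, gap_len = 15L, flank_len = 5L,
                             seed = NULL) {
  t_xyz <- as_xyz(template)
  lt <- nrow(t_xyz)
  if (lt < 6L) stop("template too short to split")
  h1 <- seq_len(lt %/% 2L)
  h2 <- (lt %/% 2L + 1L):lt
  n_total <- flank_len + length(h1) + gap_len + length(h2) + flank_len
  with_seed(seed, {
    base <- coil_coords(n_total)
    off1 <- flank_len
    off2 <- flank_len + length(h1) + gap_len
    win1 <- (off1 + 1L):(off1 + length(h1))
    win2 <- (off2 + 1L):(off2 + length(h2))
    R <- random_rotation()
    tr <- colMeans(base[c(win1, win2), , drop = FALSE]) -
      as.numeric(R %*% colMeans(t_xyz))
    sup <- structure(list(rotation = R, translation = tr),
                     class = "superposition")
    moved <- apply_superposition(sup, t_xyz)
    base[win1, ] <- moved[h1, ]
    base[win2, ] <- moved[h2, ]
    ch <- new_chain(base, structure_id = "synth_split_decoy")
    attr(ch, "offsets") <- c(off1, off2)
    attr(ch, "transform") <- sup
    ch
  })
}
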