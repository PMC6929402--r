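# Secondary-structure strings.  Each residue gets one of four states:
# H (alpha-helix), E (beta-strand), C (coil), O (other/unassigned).
# The string is the phase-1 representation of a structure; it comes
# either from a DSSP output file or from C-alpha geometry alone.

DSSP_MAP <- c(H = "H", G = "H", I = "H",   # helix subtypes fold into H
              E = "E",
              B = "C", T = "C", S = "C",   # bridge/turn/bend count as coil
              " " = "O", "-" = "O")

# Geometric classifier constants (Angstrom).  d13/d14 are the i->i+3 and
# i->i+4 CA distances typical of an alpha-helix; strand_d13 is the
# i->i+2 distance of an extended strand; tol is the acceptance window,
# and extended_min is the i->i+3 distance that separates extended
# geometry from helical winding.
sse_defaults <- function() {
  list(helix_d13 = 5.3, helix_d14 = 6.4,
       strand_d13 = 6.7, tol = 1.0, extended_min = 8.0)
}

#' Collapse DSSP 8-state codes to the 4-state alphabet
#'
#' Mapping: `H`, `G`, `I` (all helix subtypes) to `H`; `E` to `E`;
#' `T`, `S`, `B` to `C`; blank or `-` (unassigned) to `O`.
#'
#' @param dssp_states a string (or character vector of single characters)
#'   over the DSSP alphabet `H G I E B T S`, space, `-`.
#' @return A string of the same length over `{H, E, C, O}`.
#' @examples
#' map_dssp_states("HHHH")
#' map_dssp_states("GEB T-")
#' @export
map_dssp_states <- function(dssp_states) {
  chars <- if (length(dssp_states) == 1L)
    strsplit(dssp_states, "")[[1L]] else as.character(dssp_states)
  if (length(chars) == 0L) return("")
  out <- DSSP_MAP[chars]
  if (anyNA(out))
    stop("unknown DSSP state character(s): ",
         paste(unique(chars[is.na(out)]), collapse = " "))
  paste(out, collapse = "")
}

#' Read per-chain secondary structure from a DSSP output file
#'
#' Parses the classic fixed-column `.dssp` text layout (the one-letter
#' structure summary column) and returns the raw 8-state string for each
#' chain.  Chain-break records (`!`) are dropped.  Pass the result
#' through [map_dssp_states()] to obtain the 4-state alignment alphabet.
#'
#' @param path path to a DSSP output file.
#' @return Named list, one 8-state string per chain identifier.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path))
    stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("not a DSSP output file (missing residue table header): ", path)
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]                    # chain breaks
  chain <- substr(body, 12, 12)
  ss <- substr(body, 17, 17)
  split_ss <- split(ss, factor(chain, levels = unique(chain)))
  lapply(split_ss, paste, collapse = "")
}

#' Assign 4-state secondary structure from C-alpha geometry
#'
#' A deterministic, rotation/translation-invariant classifier that needs
#' nothing but the C-alpha trace.  A residue window is called helical
#' when the i to i+3 and i to i+4 distances match the alpha-helix
#' signature (5.3 and 6.4 A) within tolerance on 3 consecutive windows;
#' strand when the i to i+2 distance matches 6.7 A within tolerance on 3
#' consecutive windows and the local geometry is extended.  Residues at
#' the termini that no complete window covers are `O`; everything else
#' is `C`.  Chains shorter than 5 residues are all `O`.
#'
#' When a DSSP file is available its assignment takes precedence; this
#' geometric fallback exists so the tool runs with no external inputs
#' beyond coordinates.
#'
#' @param chain a [new_chain()] object.
#' @param params tolerances, see `sse_defaults()`.
#' @return A 4-state string of the same length as the chain.
#' @export
assign_sse_from_ca <- function(chain, params = sse_defaults()) {
  xyz <- as_xyz(chain)
  n <- nrow(xyz)
  if (n < 5L) return(paste(rep("O", n), collapse = ""))

  dk <- function(k) {
    idx <- seq_len(n - k)
    sqrt(rowSums((xyz[idx + k, , drop = FALSE] - xyz[idx, , drop = FALSE])^2))
  }
  d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)

  helix_win <- abs(d3[seq_len(n - 4L)] - params$helix_d13) <= params$tol &
               abs(d4 - params$helix_d14) <= params$tol
  strand_win <- abs(d2 - params$strand_d13) <= params$tol
  strand_win[seq_len(n - 3L)] <- strand_win[seq_len(n - 3L)] &
    d3 >= params$extended_min
  if (n >= 3L) strand_win[n - 2L] <- FALSE   # no d3 available to confirm

  lab <- rep("C", n)
  lab[c(1L, 2L, n - 1L, n)] <- "O"           # unclassifiable termini

  mark_runs <- function(win, span, code) {
    nw <- length(win)
    if (nw < 3L) return()
    run3 <- win[seq_len(nw - 2L)] & win[seq_len(nw - 2L) + 1L] &
            win[seq_len(nw - 2L) + 2L]
    for (i in which(run3))
      lab[i:min(n, i + span)] <<- code
  }
  mark_runs(strand_win, 4L, "E")
  mark_runs(helix_win, 6L, "H")              # helix wins on overlap
  paste(lab, collapse = "")
}

#' Secondary-structure string for a chain
#'
#' Convenience front end: reads and maps a DSSP file when given,
#' otherwise falls back to the geometric assigner.
#'
#' @param chain a [new_chain()] object.
#' @param dssp_file optional DSSP output file covering the chain.
#' @return 4-state string of the same length as the chain.
#' @export
sse_string <- function(chain, dssp_file = NULL) {
  if (is.null(dssp_file)) return(assign_sse_from_ca(chain))
  per_chain <- read_dssp(dssp_file)
  raw <- per_chain[[chain$chain_id]]
  if (is.null(raw))
    stop("chain '", chain$chain_id, "' not present in ", dssp_file)
  s <- map_dssp_states(raw)
  if (nchar(s) != length(chain))
    stop("DSSP string length (", nchar(s), ") does not match chain length (",
         length(chain), ")")
  s
}
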