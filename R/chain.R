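#' Construct a C-alpha chain object
#'
#' The package represents a protein chain as its ordered C-alpha trace:
#' one 3D coordinate per residue, plus residue-name and author-numbering
#' bookkeeping.  All alignment algorithms operate on the positional index
#' (1-based row of the coordinate matrix); author numbering is carried
#' along only for reporting.
#'
#' @param xyz numeric matrix with one row per residue and columns x, y, z
#'   (Angstrom).  All entries must be finite.
#' @param resname character vector of 3-letter residue codes (recycled if
#'   length 1; defaults to `"ALA"`).
#' @param structure_id identifier of the source structure (e.g. PDB code).
#' @param chain_id single-character chain identifier.
#' @param resno integer author residue numbering (defaults to `1:n`).
#' @return An object of class `ca_chain`.
#' @examples
#' ch <- new_chain(matrix(rnorm(15), ncol = 3), structure_id = "toy")
#' length(ch)
#' @export
new_chain <- function(xyz, resname = "ALA", structure_id = "", chain_id = "A",
                      resno = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("xyz must have 3 columns")
  if (nrow(xyz) < 1L)
    stop("a chain needs at least one residue")
  if (!all(is.finite(xyz)))
    stop("C-alpha coordinates must be finite")
  n <- nrow(xyz)
  if (length(resname) == 1L) resname <- rep(resname, n)
  if (length(resname) != n)
    stop("resname length must match the number of residues")
  if (is.null(resno)) resno <- seq_len(n)
  if (anyDuplicated(resno))
    stop("duplicate residue numbers in chain")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(structure_id = structure_id, chain_id = chain_id,
         xyz = xyz, resname = as.character(resname),
         resno = as.integer(resno)),
    class = "ca_chain"
  )
}

#' @export
length.ca_chain <- function(x) nrow(x$xyz)

#' @export
print.ca_chain <- function(x, ...) {
  cat(sprintf("<ca_chain> %s chain %s: %d residues\n",
              if (nzchar(x$structure_id)) x$structure_id else "<unnamed>",
              x$chain_id, length(x)))
  invisible(x)
}

# Accept either a ca_chain or a bare coordinate matrix.
as_xyz <- function(x) {
  if (inherits(x, "ca_chain")) return(x$xyz)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("expected a ca_chain or an n x 3 coordinate matrix")
  m
}
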