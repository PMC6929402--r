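# PDB chain I/O.  Parsing is delegated to bio3d; this layer reduces a
# structure to one C-alpha trace per chain and enforces the conventions
# the alignment engine relies on: first model only, first-listed altloc
# conformer, HETATM excluded, residues without a C-alpha skipped, and a
# dense 0-based positional re-index independent of author numbering.

read_pdb_atoms <- function(path) {
  if (!file.exists(path))
    stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
}

# One row per residue: first-listed CA wins among altloc/model duplicates.
dedupe_ca <- function(ca) {
  key <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  ca[!duplicated(key), , drop = FALSE]
}

#' Read one chain's C-alpha trace from a PDB file
#'
#' Extracts the ordered C-alpha coordinates of a single chain.  Only
#' `ATOM` records are considered (no HETATM); for multi-model (NMR)
#' files only the first model is used; where a residue carries alternate
#' location indicators the first-listed conformer is kept.  Residues
#' lacking a C-alpha atom are skipped.
#'
#' @param path path to a PDB-format file.
#' @param chain_id single-character chain identifier; `NULL` (default)
#'   takes the first chain in the file.
#' @return A [new_chain()] object whose residues appear in file order.
#' @seealso [list_chains()], [write_chain_pdb()]
#' @export
read_pdb_chain <- function(path, chain_id = NULL) {
  ca <- dedupe_ca(read_pdb_atoms(path))
  if (nrow(ca) == 0L)
    stop("no C-alpha atoms in ", path)
  if (is.null(chain_id)) {
    chain_id <- ca$chain[1L]
  } else if (!chain_id %in% ca$chain) {
    stop("chain '", chain_id, "' not found in ", path)
  }
  ca <- ca[ca$chain == chain_id, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("chain '", chain_id, "' has no C-alpha atoms in ", path)
  sid <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  new_chain(cbind(ca$x, ca$y, ca$z),
            resname = ca$resid,
            structure_id = sid,
            chain_id = chain_id,
            resno = ca$resno)
}

#' List the chains of a PDB file
#'
#' @param path path to a PDB-format file.
#' @return Character vector of chain identifiers having at least one
#'   C-alpha `ATOM` record, in order of first appearance (may be empty).
#' @export
list_chains <- function(path) {
  ca <- read_pdb_atoms(path)
  unique(ca$chain)
}

#' Write a C-alpha chain as a minimal PDB file
#'
#' One `ATOM` record per residue (element CA), fixed-width wwPDB layout,
#' so coordinates round-trip to 3 decimals.  An optional rigid
#' superposition is applied before writing.
#'
#' @param chain a [new_chain()] object.
#' @param path output file path.
#' @param sup optional superposition from [kabsch()] applied to the
#'   coordinates before writing.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, sup = NULL) {
  stopifnot(inherits(chain, "ca_chain"))
  xyz <- chain$xyz
  if (!is.null(sup)) xyz <- apply_superposition(sup, xyz)
  n <- nrow(xyz)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   resno = chain$resno,
                   resid = chain$resname,
                   chain = rep(chain$chain_id, n),
                   elety = rep("CA", n))
  invisible(path)
}
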