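# Text fixtures built in code: tiny hand-laid-out PDB and DSSP files.

pdb_fixture_lines <- function() {
  c("MODEL        1",
    "ATOM      1  CA AALA A   1      11.000  12.000  13.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1      99.000  99.000  99.000  0.50 10.00           C",
    "ATOM      3  CA  GLY A   2      14.000  15.000  16.000  1.00 10.00           C",
    "ATOM      4  N   GLY A   2      14.500  15.500  16.500  1.00 10.00           N",
    "ATOM      5  CA  LEU A   3      17.000  18.000  19.000  1.00 10.00           C",
    "ATOM      6  CA  SER B  10       1.000   2.000   3.000  1.00 10.00           C",
    "HETATM    7  CA   CA B  90       5.000   5.000   5.000  1.00 10.00          CA",
    "ENDMDL",
    "MODEL        2",
    "ATOM      8  CA  ALA A   1      50.000  50.000  50.000  1.00 10.00           C",
    "ENDMDL",
    "END")
}

write_pdb_fixture <- function() {
  f <- withr::local_tempfile(fileext = ".pdb",
                             .local_envir = parent.frame())
  writeLines(pdb_fixture_lines(), f)
  f
}

# Classic DSSP column layout: chain at column 12, AA at 14, SS at 17.
dssp_fixture <- function(chain, ss) {
  stopifnot(nchar(chain) == 1L)
  s <- strsplit(ss, "")[[1L]]
  c("==== Secondary Structure Definition (synthetic fixture) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d%5d %s %s  %s", seq_along(s), seq_along(s), chain,
            rep("A", length(s)), s))
}

write_dssp_fixture <- function(chain = "A", ss = "HHHHEEEE") {
  f <- withr::local_tempfile(fileext = ".dssp",
                             .local_envir = parent.frame())
  writeLines(dssp_fixture(chain, ss), f)
  f
}
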