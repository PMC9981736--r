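# Shared fixture builders. Everything is generated in code; no binary data.

# bare-bones atom record data frame
atom_df <- function(..., chain = "A", resseq = 1L, icode = "",
                    resname = "ALA", atom = "CA", element = "C",
                    bfactor = 10, occupancy = 1, altloc = "") {
  xyz <- rbind(...)
  n <- nrow(xyz)
  rec <- function(v) rep_len(v, n)
  data.frame(chain = rec(chain), resseq = rec(resseq), icode = rec(icode),
             resname = rec(resname), atom = rec(atom),
             element = rec(element), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], bfactor = rec(bfactor),
             occupancy = rec(occupancy), altloc = rec(altloc),
             stringsAsFactors = FALSE)
}

# minimal hand-written PDB text: a 3-atom glycine plus a water
mini_pdb_lines <- function() {
  c("CRYST1   10.000   20.000   30.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       2.000   2.500   3.000  1.00 20.00           C",
    "ATOM      3  C   GLY A   1       3.400   2.000   3.000  1.00 30.00           C",
    "HETATM    4  O   HOH A 101       8.000   8.000   8.000  1.00 40.00           O",
    "END")
}

# PDB fixture with an altloc pair A (occ 0.6) / B (occ 0.4) on one CB
altloc_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.400   2.400   0.000  1.00 10.00           O",
    "ATOM      5  CB AALA A   1       2.000  -1.000   1.000  0.60 12.00           C",
    "ATOM      6  CB BALA A   1       2.000  -1.000  -1.000  0.40 14.00           C",
    "END")
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# ten-residue peptide (Gly backbone) with CB only on non-Gly residues
dipeptide_gly_ala <- function() {
  # Gly (4 mainchain atoms) + Ala (4 mainchain + CB)
  rows <- rbind(
    atom_df(c(0, 0, 0), resseq = 1, resname = "GLY", atom = "N", element = "N"),
    atom_df(c(1.46, 0, 0), resseq = 1, resname = "GLY", atom = "CA"),
    atom_df(c(2.0, 1.4, 0), resseq = 1, resname = "GLY", atom = "C"),
    atom_df(c(1.4, 2.4, 0), resseq = 1, resname = "GLY", atom = "O",
            element = "O"),
    atom_df(c(3.3, 1.5, 0), resseq = 2, resname = "ALA", atom = "N",
            element = "N"),
    atom_df(c(4.2, 2.6, 0), resseq = 2, resname = "ALA", atom = "CA"),
    atom_df(c(5.6, 2.2, 0), resseq = 2, resname = "ALA", atom = "C"),
    atom_df(c(6.5, 3.0, 0), resseq = 2, resname = "ALA", atom = "O",
            element = "O"),
    atom_df(c(4.0, 3.5, 1.2), resseq = 2, resname = "ALA", atom = "CB"))
  new_structure(rows, id = "gly-ala")
}

# toy P2 crystal: one atom in a padded cell, two-fold along b
toy_p2_structure <- function(pos = c(1, 0, 0), cell = c(20, 20, 20,
                                                        90, 90, 90)) {
  new_structure(atom_df(pos, element = "C"), cell = cell,
                spacegroup = "P 1 2 1", id = "toyP2")
}

random_point_set <- function(n, scale = 10) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}

# tiny synthetic two-family alignment pair with planted specific columns
planted_family_pair <- function(n = 60) {
  base <- strrep("A", 10)
  mk <- function(col4, col7) {
    s <- strsplit(base, "")[[1]]
    s[4] <- col4; s[7] <- col7
    paste(s, collapse = "")
  }
  famA <- vapply(seq_len(n), function(i) mk("G", sample(phosphorelay:::AA20, 1)), "")
  famB <- vapply(seq_len(n), function(i) mk(sample(phosphorelay:::AA20, 1), "W"), "")
  list(A = new_alignment(stats::setNames(famA, paste0("a", seq_len(n)))),
       B = new_alignment(stats::setNames(famB, paste0("b", seq_len(n)))))
}
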