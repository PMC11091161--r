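# Canonical amino-acid bookkeeping: names, codes and heavy-atom inventories.
# Atom names follow PDB v3 conventions (CB, CG1, OD1, ...). The side-chain
# lists are used both by the typing schemes (coverage audits) and by the
# synthetic PDB writer.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

AA3_FROM_1 <- stats::setNames(names(AA1), AA1)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Side-chain heavy atoms per residue (PDB names), excluding the backbone.
SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

residue_heavy_atoms <- function(resname) {
  c(BACKBONE_ATOMS, SIDECHAIN_ATOMS[[resname]])
}

is_canonical_aa <- function(resname) resname %in% AA3

# Element symbol from a PDB atom name (heavy atoms of canonical residues).
element_from_name <- function(atom_name) {
  first <- substr(gsub("[0-9]", "", atom_name), 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S"), first, first)
}
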