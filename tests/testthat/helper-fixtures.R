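# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary files.

# hand-written PDB text exercising hydrogens, altlocs, waters and a
# non-canonical residue (MSE)
messy_pdb_lines <- function() {
  c(
    "ATOM      1  N  AALA A   1      11.000  10.000  10.000  0.60  0.00           N",
    "ATOM      2  N  BALA A   1      11.200  10.000  10.000  0.40  0.00           N",
    "ATOM      3  CA  ALA A   1      12.458  10.500  10.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1      13.500   9.700  10.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1      13.700   8.500  10.200  1.00  0.00           O",
    "ATOM      6  CB  ALA A   1      12.600  11.900  10.100  1.00  0.00           C",
    "ATOM      7  H   ALA A   1      10.500   9.300  10.000  1.00  0.00           H",
    "ATOM      8  HA  ALA A   1      12.500  10.700  11.000  1.00  0.00           H",
    "HETATM    9 SE   MSE A   2      16.000  10.000  10.000  1.00  0.00          SE",
    "HETATM   10  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "ATOM     11  N   GLY A   3      15.000  10.700  10.000  1.00  0.00           N",
    "ATOM     12  CA  GLY A   3      16.458  11.200  10.000  1.00  0.00           C",
    "ATOM     13  C   GLY A   3      17.500  10.400  10.000  1.00  0.00           C",
    "ATOM     14  O   GLY A   3      17.700   9.200  10.200  1.00  0.00           O",
    "END")
}

write_messy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(messy_pdb_lines(), path)
  path
}

toy_structure <- function(sequence = "AVGLKD", seed = 11L, geometry = "extended") {
  p <- make_pdb(sequence, geometry, seed = seed)
  standardize(read_structure(p)[[1L]])
}

# random toy environment over a fixed type set; anchor at distance 0
random_environment <- function(n = 12L, type_set = c("A", "B", "C"),
                               dmax = 10.5) {
  types <- sample(type_set, n + 1L, replace = TRUE)
  environment_from_pairs(types, c(0, sort(stats::runif(n, 0.3, dmax))),
                         type_set = type_set)
}

# reorder a cloud's rows while keeping its cloud attributes
permute_cloud <- function(cl, perm) {
  out <- as.data.frame(cl)[perm, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, scheme = attr(cl, "scheme"), type_set = attr(cl, "type_set"),
            provenance = attr(cl, "provenance"), class = class(cl))
}

all_contacts <- function(scheme = "FA") {
  comparison_settings(scheme, hetero_only = FALSE, truncation_radius = Inf)
}
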