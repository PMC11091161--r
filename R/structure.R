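#' Protein structure container
#'
#' A structure is stored as a data frame of atom records with one row per
#' atom and columns `chain`, `resnum`, `icode`, `resname`, `atom_name`,
#' `element`, `altloc`, `occupancy`, `x`, `y`, `z` plus a derived `res_key`
#' column (`chain|resnum|icode|resname`) that uniquely identifies the source
#' residue. Residue order is file order; atom order within a residue is file
#' order. The model number of the originating MODEL record is kept in the
#' `model_id` attribute.
#'
#' @param atoms data frame with the columns listed above (minus `res_key`).
#' @param model_id integer model number.
#' @return An object of class `locohd_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  needed <- c("chain", "resnum", "icode", "resname", "atom_name", "element",
              "altloc", "occupancy", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop_domain("atom table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, needed]
  if (nrow(atoms) && !all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop_domain("non-finite atom coordinates")
  }
  atoms$res_key <- residue_key(atoms$chain, atoms$resnum, atoms$icode, atoms$resname)
  rownames(atoms) <- NULL
  structure(atoms,
            model_id = as.integer(model_id),
            class = c("locohd_structure", "data.frame"))
}

residue_key <- function(chain, resnum, icode, resname) {
  paste(chain, resnum, trimws(icode), resname, sep = "|")
}

#' Residue keys of a structure, in file order
#' @param s a `locohd_structure`
#' @return character vector of unique residue keys.
#' @export
residue_keys <- function(s) unique(s$res_key)

#' Residue names corresponding to [residue_keys()]
#' @param s a `locohd_structure`
#' @return character vector of 3-letter residue names, one per residue.
#' @export
residue_names <- function(s) {
  vapply(strsplit(residue_keys(s), "|", fixed = TRUE), `[[`, "", 4L)
}

#' @export
print.locohd_structure <- function(x, ...) {
  cat(sprintf("<locohd_structure> model %d: %d residues, %d atoms\n",
              attr(x, "model_id"), length(residue_keys(x)), nrow(x)))
  invisible(x)
}

# One-letter sequence of one chain, residues in file order.
chain_sequence <- function(s, chain) {
  sub <- s[s$chain == chain, , drop = FALSE]
  keys <- unique(sub$res_key)
  res3 <- vapply(strsplit(keys, "|", fixed = TRUE), `[[`, "", 4L)
  paste(ifelse(res3 %in% AA3, AA1[res3], "X"), collapse = "")
}
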